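---
title: "Methods: permutation-forest analysis of maltreatment type and timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-forest analysis of maltreatment type and timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Retrospective maltreatment instruments in the MACE family record, for each of
10 maltreatment subscales, a weighted severity score for every life year from
1 to 18. The analytic question is which *description* of such a chronology
best predicts adult psychopathology: the type and developmental timing of
exposure (a weighted score per maltreatment type per age), or global burden
summaries that ignore timing (overall severity, multiplicity of types,
duration of exposure). Because the 64 type-by-age predictors are strongly
collinear — exposure persists across years and types co-occur — ordinary
linear regression is uninformative, and the field's standard tool is a random
forest regression with permutation-based variable importance (VI).

`maceforest` implements that analysis as a reusable pipeline:

1. **Scoring** (`build_predictor_matrix()`): 10 subscale chronologies are
   aggregated to four types (ABUSE, NEGLECT, PEER, SEXA) by averaging
   constituent subscales per year, which preserves the 0–10 range and so
   keeps types comparable. Years 1–2 are excluded from the predictors
   (infantile amnesia); the global indices keep the full 1–18 window by
   default since the exclusion argument concerns timing attribution, not
   total burden, and this choice is configurable.
2. **Importance** (`estimate_vi()`): permute-and-refit ΔMSE, averaged over
   repeated random 75/25 train/test splits.
3. **Calibration** (`build_null()`, `vi_table()`): a reshuffled-outcome null
   with one-sided Z-tests per predictor.
4. **Comparison and validation** (`competitive_compare()`,
   `select_top_per_type()`, `fit_disorder_glm()`): global-vs-specific
   contrast, and logistic validation of the strongest predictors against
   interview-based diagnosis status under a HiTOP
   internalizing/externalizing grouping of ICD-10 F-codes.

## Permute-and-refit importance

For split $r$ and predictor $j$,

$$\mathrm{VI}_j^{(r)} = \mathrm{MSE}_{\text{test}}\!\left(\hat f^{(r)}_{\pi(j)}\right) -
  \mathrm{MSE}_{\text{test}}\!\left(\hat f^{(r)}\right),$$

where $\hat f^{(r)}$ is a forest fit on the intact training data and
$\hat f^{(r)}_{\pi(j)}$ is a forest *refit from scratch* after column $j$ has
been permuted across the whole cohort (so train and test both see the broken
association). Both fits share the split, every hyperparameter, and the tree
seed, so the only difference is the destroyed predictor–outcome association.
`vi_mean` is the average over `n_split_reps` (default 100) splits. We refit
rather than use the cheaper out-of-bag shuffle because the refit variant is
the literal published procedure this pipeline reproduces; it is also the
reason compute scales as (p + 1) forest fits per split. Negative ΔMSE values
are sampling noise and are deliberately retained so the null distribution
stays unbiased.

The base learner is a `ranger` regression forest behind a thin
`fit_forest()` contract. The default split criterion is `"maxstat"`
(maximally selected rank statistics), the unbiased association-test style of
splitting used by conditional-inference forests, which avoids the variable-
selection bias of exhaustive variance-reduction search when predictors differ
in scale and number of distinct values; `"variance"` is available and is used
in some tests where speed matters more than split-selection bias. Exact
numerical agreement with any particular conditional-forest implementation is
a non-goal. Hyperparameter defaults (`n_trees = 500`,
`predictors_per_node = ceiling(sqrt(p))`, `min_node_size = 5`) are
conventional forest defaults, exposed in `forest_config()` and recorded in
the run manifest. Missing values are refused, not imputed.

## The reshuffled-outcome null and its scale correction

Significance comes from rerunning the VI procedure on outcome vectors
permuted across subjects: under this null every predictor–outcome
association is destroyed while the predictor matrix, its collinearity, and
the forest machinery are untouched. The full-fidelity analysis uses 5,000
reshuffles; scaled-down runs use fewer (`n_null_reps`).

A subtlety matters here. The *observed* statistic is a mean over $R$ splits
(default 100), but rerunning all $R$ splits inside each of thousands of null
replicates is prohibitively expensive. If each null replicate instead uses a
single split and its raw SD is plugged into the Z-test, the test is badly
miscalibrated: the variance of a single-split VI is dominated by split-and-
forest noise $V_s$, which the observed $R$-split average suppresses by $1/R$.
In our null simulations the resulting Z-scores had an empirical SD near 0.33
instead of 1, i.e. essentially nothing can ever reach significance.

`build_null()` therefore runs each null replicate with $k \ge 2$ splits
(default $k = 2$) and separates the two variance components: the mean
within-replicate variance estimates $V_s$, the variance of replicate means
estimates $V_u + V_s/k$ (with $V_u$ the reshuffle-level variance), and the
null SD reported for the Z-test is

$$\widehat{\mathrm{sd}}_0 = \sqrt{\max\!\left(\widehat{\mathrm{Var}}(\bar{\mathrm{VI}}_b)
  - \hat V_s\!\left(\tfrac1k - \tfrac1R\right),\; \hat V_s/R\right)},$$

the SD the null VI *would* have if every replicate averaged $R$ splits. With
$k = R$ the correction vanishes, so the full-fidelity setting is a special
case rather than a different formula. Setting `null_split_reps = 1` recovers
the naive scheme (with a warning) for comparison. Under complete-null
simulations the corrected Z-scores have unit SD and the flag rate at
$\alpha = 0.05$ sits inside binomial bounds of 0.05 (the test suite checks
this over 50 cohorts).

The Z-test is one-sided (upper tail): only an importance *above* chance is
evidence. No multiple-testing correction is applied by default, matching the
per-predictor reporting convention of this literature; `vi_table(adjust =
"BH")` provides Benjamini–Hochberg when wanted. A predictor whose null SD is
exactly zero (e.g. a constant column) is flagged `degenerate` with `NA`
p-value rather than silently tested.

## Competitive testing and validation

`competitive_compare()` contrasts the largest `vi_mean` among
{SEVERITY, MULTI, DURATION} with the largest among the 64 type-by-age
predictors and reports the direction; exact ties break lexicographically and
are flagged. `select_top_per_type()` picks, per CM type, the significant cell
with maximal importance; types with no significant cell are omitted.

Because the specific group contains 64 predictors, the maximum of its VI
estimates carries a noise floor that shrinks only with the number of averaged
splits; a weakly planted global effect can be out-ranked by that floor even
when no timing signal exists, and a global index whose signal is largely
recoverable from its collinear companions (in the default generator,
cor(SEVERITY, MULTI) ≈ 0.88) earns a refit-VI well below its planted share.
The package's flip experiment — verifying that the verdict moves from
"global dominates" to "specific dominates" as a timing effect grows with
global burden held fixed — is therefore run with a firmly planted global
effect (weight 8 on SEVERITY) and 50 splits, sizes chosen so the two group
maxima separate cleanly from that noise floor.

Selected predictors are validated against diagnosis status with one binomial
GLM each — outcome regressed on the (z-scored) predictor plus sex and age —
rather than one joint model, matching the predictor-wise odds-ratio
reporting style of the source analyses. Standardizing the predictor makes
odds ratios per-SD and hence comparable across predictors of very different
scales; `standardize = FALSE` keeps the raw scale. Quasi-separation is
detected and flagged, not hidden. ICD-10 F-codes map to spectra by
longest-prefix match, so the most specific printed pattern wins
(F60.31 → internalizing although F60.3 → externalizing); the externalizing
range F10–F25 includes the psychotic stems F20–F25 as printed in the
grouping this pipeline reproduces, which is documented rather than "fixed".

## The synthetic cohort generator

Real MACE chronologies from the target population are protected, so the
package ships a generator whose defaults emulate a high-risk young-adult
cohort formerly in residential care (n = 185, 34% female, age 26.4 ± 3.5):

* **Prevalence curves** (per subscale, per age): neglect near ceiling (0.90
  at every age), sexual abuse rare (0.06), peer violence rare before age six
  (0.04) ramping to ~0.30 in adolescence, parental-abuse subscales humped in
  early/middle childhood (peak ~0.45 around age seven). These reproduce the
  qualitative prevalence profile reported for such cohorts; no per-age
  numeric table is public, so the curves aim at qualitative fidelity only.
* **Persistence** (default 0.9): exposure in year $t$ continues in year
  $t+1$ with probability $p_{t+1} + \rho(1 - p_{t+1})$; the unexposed-state
  conditional is solved so the marginal prevalence curve is hit *exactly*
  (clamped to [0,1] when a steeply falling curve makes the exact solution
  infeasible). $\rho$ is therefore an excess-continuation parameter, not the
  raw continuation probability, which keeps marginals interpretable.
* **Co-occurrence**: a Gaussian copula on year-level latents with
  correlation 0.5 within a type and 0.25 across types (positive
  semidefinite by construction). The mechanism is a modelling choice; only
  the *fact* of interrelated types is documented for the real instrument.
* **Severity given exposure**: $0.5 + 9.5 \cdot \mathrm{Beta}(2, 5)$ (right-
  skewed, mean ≈ 2.9), left-truncated so every exposed subscale-year scores
  above the default exposure threshold of 0.5 — this makes "exposed" and
  "above threshold" coincide, which keeps prevalence parameters directly
  interpretable. A degenerate `list(value = v)` form exists for exact
  ceiling tests.
* **Outcomes**: $T = 50 + \sum_j w_j z(x_j) + \varepsilon$,
  $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$ with `noise_sd = 10` T-score
  units; planted effects `effect_map` act on within-cohort z-scored
  predictors, so a weight $w$ with noise 10 yields the analytic
  predictor–outcome correlation $w/\sqrt{w^2 + 100}$. Diagnoses are
  Bernoulli through a logistic link sharing the same linear predictor
  (intercepts default to population rates of 61% / 32% / 54% for
  any / internalizing / externalizing); self-report and interview outcomes
  are thus consistent by construction, separable via the spec.
* Sex and age influence outcomes only if named in `effect_map`.

What the generator does **not** emulate: item-level questionnaire structure
(75 items per instrument), reporting and recall biases, severity
autocorrelation beyond the exposure indicator, age-dependent severity
distributions, comorbidity structure beyond a shared linear predictor, and
missingness. Passing tests therefore demonstrate that the *pipeline*
recovers what it should under its assumed data-generating process — not that
those assumptions hold in any real cohort.

## Thresholds and open scoring choices

The validated per-subscale exposure thresholds used with the real instrument
are published elsewhere and not restated here; `threshold_table()` defaults
to 0.5 on the 0–10 scale (any non-negligible exposure counts) and accepts
user-supplied published values (`read_thresholds()`). A subscale's "overall
severity" — the quantity summed into SEVERITY (0–100) and thresholded for
MULTI — is implemented as the mean of its per-year scores over the
configured window: this is range-preserving, monotone under added exposure,
and reduces to the per-year score for a constant chronology. Summing raw
year scores instead would leave the documented 0–100 range unexplained,
which is why the mean convention was chosen.

## Reproducibility and problem sizes

Every stage derives its RNG streams from one master seed via labelled
sub-seeds (`derive_seed()`), so a fixed seed yields bit-identical cohorts,
splits, permutations, trees, and output files; `run_pipeline()` writes a
manifest with the seed and a configuration hash, and per-outcome seeds use a
counter scheme on the outcome label so adding an outcome never perturbs the
others.

The shipped tests and the acceptance script run the procedure at reduced
problem sizes chosen as the package's own working points: forests of 15–25
trees, 25 splits, 200 null replicates, cohorts of 120–2000, a reduced
4-predictor matrix for the null-calibration study and the full 69-predictor
matrix for planted-effect recovery. These sizes keep the full suite
runnable on a laptop core while leaving every statistical property intact;
the full-fidelity configuration (500 trees, 100 splits, 5,000 null
replicates) is reached purely through `forest_config()` /
`run_config()` arguments.

## Known limitations

* Permute-and-refit importance inherits the usual behaviour of marginal
  permutation importance under collinearity: permuting one of several
  correlated carriers of a signal understates each carrier's importance.
  The competitive global-vs-specific contrast compares group *maxima*, which
  is robust to this within groups but still conservative overall.
* The null-SD correction assumes split-level VI draws are conditionally
  independent given a reshuffle; trees and splits share the cohort, so this
  is an approximation (empirically adequate in calibration simulations).
* The generator's planted diagnosis link uses the same linear predictor as
  the continuous outcomes; GLM validation on synthetic data is therefore a
  parameter-recovery check, not evidence about real diagnostic processes.
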