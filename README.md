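# maceforest

Does *what kind* of childhood maltreatment a person experienced, and *when*,
predict adult psychopathology better than *how much* of it they experienced
overall? `maceforest` implements the standard analysis pipeline for this
question as used with MACE-style retrospective chronologies (10 maltreatment
subscales, weighted severity 0–10 per life year 1–18) in clinical and
high-risk cohorts. It is aimed at researchers in developmental
psychopathology and psychiatric epidemiology who want the full procedure —
scoring, forest-based importance, permutation-null inference, competitive
testing, and diagnostic validation — as tested, seeded, reusable code.

## The method

**Predictors.** Subscale chronologies are averaged into four maltreatment
types — parental abuse (ABUSE), parental neglect (NEGLECT), peer violence
(PEER), sexual abuse (SEXA) — per age 3–18 (ages 1–2 are dropped as
unreliable), giving 64 type-by-age scores on a common 0–10 scale, plus three
global burden indices: SEVERITY (0–100, summed subscale severity), MULTI
(0–10, subscales above threshold), DURATION (0–18, years with any
above-threshold exposure), plus sex and age.

**Importance.** For predictor *j* on one random 75/25 train/test split,

> VI_j = MSE_test(forest refit with column *j* permuted across the cohort) −
> MSE_test(forest fit on intact data),

averaged over repeated splits (default 100). Permuting an important predictor
degrades the refit forest; permuting an irrelevant one does not. Forests are
`ranger` ensembles with unbiased maximally-selected-rank splitting by
default, which tolerates the strong collinearity of adjacent-year scores.

**Inference.** The whole VI procedure is rerun on outcome vectors reshuffled
across subjects (full fidelity: 5,000 reshuffles) to obtain each predictor's
chance VI distribution; a one-sided Z-test flags predictors whose observed VI
exceeds chance. The null SD is variance-decomposed so that cheap few-split
null replicates are put on the scale of the many-split observed average
(see the methods vignette — without this correction the test is far too
conservative).

**Comparison and validation.** `competitive_compare()` contrasts the best
global index against the best type-by-age predictor per outcome;
`select_top_per_type()` picks the strongest significant cell per type; and
`fit_disorder_glm()` validates selections against interview-based diagnosis
status (ICD-10 F-codes grouped into HiTOP internalizing / externalizing
spectra) with per-predictor logistic models controlling for sex and age.

Because real chronologies from the target population are protected, the
package includes a synthetic-cohort generator (`synthetic_spec()`,
`generate_cohort()`) with realistic prevalence curves, year-to-year
persistence, cross-type co-occurrence, and plantable effects, so every stage
is testable end to end.

## Worked example

A cohort of 300 subjects with a planted timing effect (parental abuse at age
six, weight 5 T-score units per SD) on top of a global severity effect
(weight 3), analysed with a scaled-down configuration:

```r
library(maceforest)

spec <- synthetic_spec(n_subjects = 300,
                       effect_map = c(ABUSE_06 = 5, SEVERITY = 3),
                       noise_sd = 10, logistic_slope = 0.2, seed = 42)
coh <- generate_cohort(spec)
x <- coh$predictors[, setdiff(names(coh$predictors), "subject_id")]
y <- coh$outcomes$t_total

cfg  <- forest_config(n_trees = 50, n_split_reps = 10, seed = 42)
vi   <- estimate_vi(x, y, cfg)                    # 69 predictors
null <- build_null(x, y, cfg, n_null_reps = 50)   # reshuffled-outcome null
tab  <- vi_table(vi, null)
head(tab[order(-tab$z), c("predictor", "vi_mean", "null_mean", "null_sd", "z", "p")], 5)
#>    predictor   vi_mean   null_mean   null_sd        z            p
#> 4   ABUSE_06 7.4612945  0.42295030 0.8001745 8.796012 7.088237e-19
#> 68       sex 1.4325639  0.05499542 0.4542833 3.032399 1.213090e-03
#> 7   ABUSE_09 1.7329847 -0.08771574 0.7233038 2.517200 5.914578e-03
#> 39   PEER_09 0.9085348 -0.24313971 0.4739769 2.429811 7.553345e-03
#> 49   SEXA_03 0.5172762 -0.07498393 0.2629521 2.252350 1.215009e-02
```

The planted cell tops the table: permuting `ABUSE_06` costs the forest ~7.5
MSE units against a chance level of ~0.4 ± 0.8, z ≈ 8.8. The timing effect
out-ranks the global indices, and the strongest significant cell per type is
then validated against diagnosis status:

```r
competitive_compare(tab)$verdict
#> [1] "specific dominates"

glm_data <- cbind(coh$predictors,
                  coh$outcomes[setdiff(names(coh$outcomes), names(coh$predictors))])
fit_disorder_glm(glm_data, "ABUSE_06", "dx_any")[, c("predictor", "beta", "se", "or", "p")]
#>   predictor     beta        se       or           p
#> 1  ABUSE_06 1.603093 0.1972704 4.968376 4.42326e-16
```

i.e. one SD more abuse at age six multiplies the odds of any current
diagnosis by ~5 in this synthetic cohort (controlling for sex and age).
Descriptive effect sizes from group summary statistics use `welch_cohen()`:

```r
welch_cohen(48.97, 9.45, 73, 57.46, 10.31, 112)$d
#> [1] -0.85066
```

`run_pipeline(run_config(...), out_dir)` chains all stages for the three
outcomes (total / internalizing / externalizing problems) and writes
per-outcome VI tables, GLM results, descriptives, and a manifest that makes
reruns byte-identical; `inst/cli/maceforest.R` exposes the same stages as
shell subcommands.

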