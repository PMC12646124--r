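Package: maceforest
Title: Type- and Timing-Specific Effects of Childhood Maltreatment via
    Permutation Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for retrospective childhood-maltreatment (CM)
    chronologies and adult psychopathology. Scores MACE-style exposure
    chronologies into weighted type-by-age predictors and global burden
    indices (SEVERITY, MULTI, DURATION), estimates each predictor's
    importance for continuous symptom outcomes with a permute-and-refit
    random-forest procedure averaged over repeated 75/25 train/test splits,
    attaches significance through a reshuffled-outcome null distribution and
    Z-tests, competitively compares global against type- and timing-specific
    CM measures, and validates selected predictors against interview-based
    diagnosis status (ICD-10 codes grouped into HiTOP internalizing and
    externalizing spectra) with binomial generalized linear models. Includes
    a synthetic-cohort generator with configurable prevalence curves,
    year-to-year persistence, cross-type co-occurrence, and planted effects,
    so the full pipeline is testable without protected participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
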