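Package: vocortisol
Title: Predicting Diurnal Urinary Cortisol from Volatile Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for modelling total free urinary cortisol
    from untargeted GCxGC-TOFMS volatile-metabolite feature tables.
    Implements probabilistic quotient normalization and log10
    centre/scale preprocessing with presence, blank and retention-time
    filters; a two-way ANOVA factor screen; bootstrapped elastic-net
    stability selection over subject-level resamples; forward/backward
    stepwise regression with sex and time-of-day interaction terms under
    AICc/BIC minimization; regression diagnostics (VIF, added-variable
    data, residual summaries, subgroup t-tests with FDR control); a
    frozen 22-coefficient published predictor with microgram
    back-transformation; Kovats-style retention indexing with MSI
    identification-confidence levels; and a synthetic cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    car,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
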