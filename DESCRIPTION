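Package: dspscore
Title: Construction and Diagnostic Evaluation of the Difficult
    Spinal-Arachnoid Puncture (DSP) Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds additive integer clinical risk scores from model
    coefficient tables (significance filter, nearest-integer weighting,
    sign-directed level assignment), applies them to per-procedure patient
    records, and evaluates their diagnostic performance: discrete-score ROC
    curves with trapezoidal AUC and Hanley-McNeil confidence intervals,
    Youden's J and prevalence-weighted efficiency cutoff selection, and full
    2x2 diagnostic statistics with Clopper-Pearson, Simel log-method and
    Mercaldo logit confidence intervals, including prevalence-adjusted
    predictive values. Ships the Difficult Spinal-Arachnoid Puncture (DSP)
    Score as the built-in model, a reconstruction of its 300-procedure index
    cohort from grouped operating points, and a seeded synthetic-cohort
    generator with a logistic latent difficulty model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
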