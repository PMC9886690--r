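Package: fallbma
Title: BIC-Weighted Bayesian Model Averaging for Instrumented Fall-Risk
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exhaustive all-subsets logistic regression with BIC-weighted
    Bayesian model averaging over instrumented stand-and-walk (ISAW)
    balance and gait metrics, for discriminating prospective fallers from
    non-fallers in older adults.  Provides posterior inclusion
    probabilities, model-averaged coefficients and predicted risks,
    ROC/AUC machinery with bootstrap and DeLong confidence intervals, an
    AUC-versus-BIC model frontier, descriptive group comparisons
    (summary-statistic t-tests, fall-status cross-tabulation, dual-task
    cost), and a seeded synthetic cohort generator calibrated to published
    group-level summary statistics so the full pipeline is testable
    without access-controlled per-participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
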