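Package: telecopd
Title: Telemonitoring-Based Prediction of COPD Exacerbation Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating next-day prediction of hospital admission and
    corticosteroid initiation from daily COPD telemonitoring records. Implements
    the classical symptom-counting exacerbation definitions (Anthonisen-style
    major/minor symptom rules), a configurable synthetic-cohort simulator with a
    latent exacerbation process and known ground-truth risk, sliding-window
    patient-episode construction under complete-data and forward-fill-imputed
    scenarios, a catalogue of time-series features, a uniform interface over
    regularized linear, kernel max-margin and boosted-tree classifiers, and
    patient-grouped nested cross-validation with aggregated AUC, DeLong /
    bootstrap / Chebyshev confidence intervals and ROC operating points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
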