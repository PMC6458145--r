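Package: dife
Title: Development and Validation Toolkit for the Dialysis Initiation Fuzzy
    Equation (DIFE) Risk Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating the DIFE, a fuzzy-mathematics
    risk score for timing haemodialysis initiation in end-stage renal disease.
    Provides the scoring equation with its sigmoid weighting multiplier,
    Chinese-modified MDRD and CKD-EPI eGFR calculators, a kernel
    logistic neural network with restricted-Boltzmann-machine pretraining for
    variable-subset selection, particle swarm optimization for fitting the
    score parameters to a development cohort, candidate-threshold selection,
    and a validation suite (confusion metrics, bootstrap ROC comparison,
    Kaplan-Meier curves with log-rank tests, mortality rates per 100
    patient-years, and a logistic comparator with Hosmer-Lemeshow
    calibration). Includes a synthetic ESRD cohort generator with a known
    ground-truth risk process for end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
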