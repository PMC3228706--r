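Package: icudischarge
Title: Gaussian Process Prediction of ICU Discharge After Cardiac Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Early prediction of intensive-care-unit discharge after scheduled
    cardiac surgery from the first four hours of routinely captured patient
    data. Provides a seeded synthetic cohort generator emulating a patient
    data management system (admission covariates, cumulative medication,
    repeated laboratory results, per-minute physiological signals, fluid
    balance, discrete day of discharge); feature extraction with mean
    imputation, peak-shaving artifact removal, linear interpolation, 40-minute
    window statistics and approximate entropy; per-category Gaussian-process
    submodels (exact regression for the discrete day of discharge,
    Laplace-approximate classification with a logistic link for second-day
    discharge) with automatic-relevance-determination kernels, integrated by
    stacked generalization; an additive-risk-score baseline; and an evaluation
    suite (area under the ROC curve with the DeLong test, Brier score with its
    reliability/resolution/uncertainty decomposition and a paired bootstrap
    comparison, Hosmer-Lemeshow calibration, loss penalty function, root mean
    squared relative error and discharge-day prevalence tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
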