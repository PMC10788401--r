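Package: recanflow
Title: Spatiotemporal Hemodynamic Features and Recanalization Prediction
    for Coiled Intracranial Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the spatiotemporal definition of
    hemodynamic parameters affects prediction of aneurysm recanalization
    after coil embolization. Generates synthetic patient cohorts with
    pulsatile, time-resolved hemodynamic fields standing in for
    computational fluid dynamics output; extracts 91 spatiotemporal
    features (spatial average/maximum crossed with seven temporal
    descriptors for six field parameters, plus inflow-rate-ratio
    descriptors) together with morphological ratios; screens group
    differences with Levene-gated t-tests and Yates-corrected chi-square
    tests; evaluates every feature as a univariate predictor via
    ROC/precision-recall analysis with DeLong paired AUROC comparisons
    and stratified bootstrap confidence intervals; and fits a
    multivariate logistic regression through a standardize, univariate
    screen, VIF filter, SMOTE rebalancing and backward stepwise
    selection pipeline, with Hosmer-Lemeshow calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
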