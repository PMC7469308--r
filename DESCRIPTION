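Package: thyroRisk
Title: Ultrasonographic Risk Scoring and Stratification of Thyroid Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Malignancy risk scoring for thyroid nodules from
    ultrasonographic characteristics. Provides per-characteristic diagnostic
    metrics (sensitivity, specificity, predictive values, AUC) from
    one-vs-rest contingency tables, echogenicity-ratio cutoff optimisation,
    L1-penalized logistic regression with cross-validated penalty selection
    for characteristic screening over repeated stratified splits,
    repetition-averaged classifier risk scores, and a four-category risk
    stratification with bootstrap-percentile and ROC-derived thresholds.
    Includes a calibrated synthetic cohort generator so the full pipeline is
    reproducible without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
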