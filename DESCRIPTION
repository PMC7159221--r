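Package: readmitr
Title: Readmission Risk Prediction and Hospital Risk Standardization with
    Medical Code Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts 30-day unplanned hospital readmission from
    administrative claims and computes risk-standardized hospital
    readmission rates. Implements GloVe-style embeddings of diagnosis and
    procedure codes from record-level co-occurrence, four competing risk
    models (hierarchical logistic regression, gradient-boosted trees, a
    feed-forward network, and a permutation-invariant deep-set network on
    code embeddings), predictive-margin and predicted-over-expected risk
    standardization, quintile (20/60/20) hospital grouping and
    reclassification analysis, and a synthetic claims generator that
    emulates the statistical structure of all-payer readmission databases
    so the full pipeline is testable without restricted data.
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
    lme4,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
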