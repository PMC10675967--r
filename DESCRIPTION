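Package: hosplasso
Title: LASSO Variable Selection for Hospital-Clustered Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Penalized variable selection for patient-level outcomes nested
    within hospitals. Implements three LASSO variants for clustered data --
    ignoring hospitals, hospitals as penalized fixed-effect dummies, and an
    L1-penalized random-intercept (mixed) model fitted by a working-response
    coordinate-descent scheme -- together with the supporting machinery: a
    synthetic clustered-data generator, the data-preparation rules
    (log-transform, pairwise-correlation filter, per-split zero-variance
    removal, unit-variance scaling), penalty-grid construction with certified
    null-model and first-five-values rules, tuning by cross-validation
    (lambda_min, lambda_1se) or AIC/BIC, a hospital-coverage-constrained
    sub-sampling evaluation with RMSE, AUC, AUPRC, Brier score and predictive
    Bernoulli likelihood, and a top-5 stability-based variable-importance
    statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    knitr,
    lme4,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
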