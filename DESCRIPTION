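Package: rfalasso
Title: Two-Step Random-Forest Screening and Adaptive Lasso for Chemical
    Mixture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the joint health effects of correlated
    chemical-mixture exposures. Implements a two-step procedure in which
    random-forest permutation variable importance screens candidate
    exposures before an adaptive lasso (weighted L1 penalty) with
    two-dimensional (gamma, lambda) cross-validation quantifies main and
    pairwise interaction effects, together with comparator workflows
    (single-step adaptive lasso; CART screening followed by adaptive
    lasso), exposure-table preprocessing (limit-of-detection imputation,
    missingness filtering, log and z-score standardization), simulation
    designs with block-equicorrelated predictors, and cross-validated
    performance evaluation (R-squared, adjusted R-squared, MSE, and
    fold-weighted mean squared prediction error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
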