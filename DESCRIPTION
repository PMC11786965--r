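Package: pvglasso
Title: Pseudo-Variable Assisted Ensemble Feature Selection for Survival Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble feature selection for high-dimensional right-censored
    survival data. Rankings from several base selectors (univariate Cox,
    L1-penalized Cox, mutual information maximization, minimum-redundancy
    maximum-relevance) are aggregated, the aggregated feature set is
    partitioned into correlation blocks, and blocks are selected with a Cox
    proportional-hazards group lasso whose tuning is controlled by permuted
    pseudo-variables acting as negative controls. Includes survival-data
    simulators with event-rate calibration, a metric suite (FDR, sensitivity,
    F1, Jaccard stability, empirical power, weighted relative frequency,
    concordance index, integrated Brier score), and a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    survival,
    glmnet,
    MASS,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
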