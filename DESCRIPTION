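Package: dynalocus
Title: Regularized Blind Source Separation for Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes multi-subject dynamic functional connectivity (dFC)
    matrices into sparse, low-rank latent connectivity traits and temporally
    smooth trait-loading time series. Implements tapered sliding-window dFC
    construction with Fisher z transformation, SVD-based dimension reduction
    and whitening, a block-multiconvex node-rotation estimation algorithm
    with angle-based element-wise sparsity and temporal smoothness
    regularization, adaptive trait-specific rank selection, BIC-type and
    reconstruction-error tuning, bootstrap reliability indices with greedy
    component matching, temporal dynamics metrics (energy, variation,
    lagged cross-correlation synchronization), whole-brain dFC state
    identification by k-medians clustering of trait loadings, and a
    synthetic-data harness for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
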