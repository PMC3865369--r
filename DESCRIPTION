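Package: jcggm
Title: Joint Conditional Gaussian Graphical Models for Multi-Condition
    Genetical Genomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of condition-specific gene-network precision
    matrices from multi-tissue expression data measured together with genetic
    markers. Covariate (marker) effects are conditioned out with a kernel
    conditional covariance estimator; the precision matrices are then
    estimated jointly by penalized profiled likelihood with a nonconvex
    truncated-log joint-sparsity penalty, optimized by local linear
    approximation over weighted graphical-lasso subproblems and tuned by BIC.
    Includes a genetical-genomics simulation engine (backcross genotypes on a
    genetic map, scale-free networks, hotspot expression models), support
    recovery and Frobenius-loss evaluation metrics with ROC paths, and a
    permutation-calibrated single-marker eQTL scan for covariate selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
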