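Package: slesa
Title: Spatially Localized Ensemble Sparse Analysis for Two-Class Image ROI Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies square grayscale regions of interest (ROIs), such as
    mammographic mass patches, into two classes by spatially localized
    ensemble sparse analysis (SLESA). Each ROI is decomposed into a grid of
    blocks; every block position gets its own overcomplete dictionary built
    from training blocks, optionally refined by label-separated KSVD
    (LS-SLESA) or label-consistent KSVD2 (LC-SLESA) dictionary learning.
    Test blocks are sparse-coded with orthogonal matching pursuit and the
    per-block class evidence is fused by majority-vote (BBMAP) or mean
    log-likelihood (BBLL) decision functions based on class-wise sparsity
    masses or reconstruction residuals. Includes a synthetic textured-mass
    generator, stratified k-fold cross-validation, grid search, ROC/AUC
    metrics and DeLong's paired AUC test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
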