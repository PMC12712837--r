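Package: bbspls
Title: Sparse Partial Least Squares Signatures Linking Blood Markers and
    Brain Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-level machine-learning pipeline for multivariate
    blood-brain association studies. Level one extracts sparse partial
    least squares (SPLS) latent variables linking a blood-parameter view
    to a voxelwise gray-matter-volume view inside a group-stratified
    nested cross-validation, with out-of-sample latent-score correlation
    as the selection criterion, permutation significance, bootstrap-ratio
    feature stability, multi-site ComBat harmonization and projection
    deflation. Level two groups participants by quartile conjunction of
    their latent scores and classifies high versus low scorers from
    clinical predictor domains with a repeated nested-CV linear SVM
    optimized on balanced accuracy, label-permutation significance and
    sign-based-consistency feature selection. A seeded synthetic-data
    generator with planted sparse latent structure, site effects and
    missingness provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    sva,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
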