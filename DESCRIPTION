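Package: gbabias
Title: Multifunctionality Bias Auditing for Guilt-by-Association Gene
    Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to measure, exploit, and control for multifunctionality
    (node-degree) bias in guilt-by-association gene function prediction.
    Provides per-gene multifunctionality scores and the AUROC-optimal fixed
    gene ranking they induce, node-degree predictors, individual property
    networks built from the self-outer product of the degree vector,
    neighbor-voting prediction with cross-validation, degree-preserving
    network null models with per-group empirical p-values, annotation
    semantic-similarity audits of network links, and a synthetic-data
    generator with controlled coupling between degree propensity and
    multifunctionality. Reads gene-set collections (GMT, GAF/OBO) and gene
    networks (edge lists, dense matrices, MatrixMarket), and builds
    coexpression networks from expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
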