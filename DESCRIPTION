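Package: morphnet
Title: Single-Subject Gray-Matter Morphological Connectomes and Their Analysis
Version: 0.1.0
Authors@R:
    person("Morphnet", "Developers", email = "morphnet@example.org", role = c("aut", "cre"))
Description: Builds single-subject gray-matter morphological brain networks by
    comparing regional intensity distributions with a Kullback-Leibler
    divergence based similarity (KLS), characterizes the resulting connectomes
    with sparsity-swept graph-theory metrics (small-world parameters, network
    efficiency, nodal centralities) summarized by area under the curve, tests
    group differences by permutation with Benjamini-Hochberg false discovery
    rate control, correlates network metrics with clinical scales via
    covariate-adjusted partial correlation, and classifies diagnostic groups
    with a reducer-by-classifier cascade (autoencoder / neural-network
    reduction; support vector machine, random forest, gradient boosting)
    under stratified cross-validation with Gaussian-process confound
    residualization. A synthetic cohort generator makes the whole pipeline
    exercisable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
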