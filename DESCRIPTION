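Package: bmvae
Title: Clustering Single-Cell Binary Mutation Data with a Variational
    Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers tumor subpopulations from noisy binary single-cell
    mutation matrices in three stages: a variational autoencoder embeds
    each cell's mutation profile into a low-dimensional latent space with
    masking of missing entries, a Gaussian mixture model clusters cells in
    that space with the number of clusters selected by BIC under a patience
    rule, and a Gibbs sampler estimates each subpopulation's binary
    genotype together with global false-positive and false-negative error
    rates. Includes a synthetic-data simulator with clonal-tree structure,
    doublets and missing data, plus evaluation metrics (adjusted Rand
    index, genotyping accuracy) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1),
    mclust
Imports:
    data.table,
    Rcpp,
    stats,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
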