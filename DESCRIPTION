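Package: scstate
Title: Sequential Cell State Classification from Single-Cell Expression via
    Message Passing and Ordinal Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies cells into ordered (sequential) biological states from
    raw single-cell RNA-seq count matrices. Each cell is represented as a gene
    graph whose directed edges carry radial-basis-featurized pairwise
    log-ratios of expression counts and whose nodes carry prior gene-embedding
    vectors (a dual-layer design). A message passing neural network
    encoder-decoder learns cell embeddings, a masked gene-embedding
    reconstruction objective with an entropic optimal-transport loss
    regularizes the representation, and an ordinal-regression head with
    conditional training subsets exploits the ordering of adjacent cell
    states. Includes quality-control filters, highly-variable-gene selection,
    readers for CSV/MatrixMarket/h5ad count matrices, a negative-binomial
    synthetic generator of ordered cell states, a stratified cross-validation
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
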