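Package: sagnet
Title: Co-Occurrence Networks and Cross-Feeding Analysis for Single-Cell
    Genome Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for communities of single amplified genomes
    (SAGs): quality filtering and completeness-corrected genome size
    estimation, log-log scaling analysis of coding-sequence counts against
    genome size, CAZyme presence/absence profiles with Jaccard functional
    distances and per-family enrichment tests, compositionally aware
    (SparCC-type) correlation inference from abundance tables with
    permutation significance, thresholded co-occurrence networks partitioned
    into sub-communities, null-model standardized effect sizes for
    modularity, rarefaction-based density comparisons, and aggregation of
    SMETANA-style metabolite exchange scores into sub-community sum and
    size-normalized scores with metabolite-category profiling and PCA.
    Includes seeded synthetic-data generators with planted, recoverable
    structure for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
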