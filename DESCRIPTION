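Package: prophy
Title: Whole-Proteome Phylogenies from Average Sequence Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs phylogenies from whole proteomes using an
    average sequence similarity statistic. For every query ORF of one
    organism the E-value of its best local-alignment hit in another
    organism is compared, on a log scale, with the E-value of the query
    matched against itself; the slope of an origin-constrained
    least-squares fit through these points gives a directed average
    similarity T, and pairwise distances D = 1 - (T_xy + T_yx)/2 feed
    neighbor-joining or BioNJ tree reconstruction. Includes a compiled
    Smith-Waterman search engine with Karlin-Altschul E-values, a parser
    for precomputed 12-column tabular search results, a saturation
    correction calibrated by simulated mutation, and an in-silico
    proteome evolution simulator (per-generation residue mutation,
    balanced lineage trees, lateral gene transfer) used to validate the
    method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
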