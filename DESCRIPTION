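Package: hugeprot
Title: Survey of Huge Proteins in Proteome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to survey huge proteins (sequences of at least 5000 amino
    acids) across collections of proteomes: extraction and per-phylum
    prevalence statistics, existence-level comparison with fixed-size
    resampling, greedy identity/coverage sequence clustering built on a
    native affine-gap Smith-Waterman aligner, Pfam domain-architecture
    fingerprinting from HMMER domtblout files, aggregation of disorder,
    signal-peptide, transmembrane and Gene Ontology annotations with
    artifact flagging, and a synthetic proteome generator providing ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
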