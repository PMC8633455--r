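Package: mirwood
Title: Discovery, Differential Expression and Target Integration of
    Plant Stem Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for plant small-RNA sequencing studies
    of developing stems: read cleaning, annotation of sequence tags into
    structural RNA classes, identification of existing and conserved
    miRNAs against a miRBase-style catalogue, prediction of novel miRNA
    hairpins under MIREAP-style structural criteria with an internal
    minimum-free-energy folding engine, negative-binomial exact tests for
    differential expression across three developmental stages, weighted
    mismatch miRNA target prediction with a duplex energy-ratio filter,
    Pearson-correlation integration of miRNA-target pairs, and
    hypergeometric term enrichment. Includes a synthetic-data generator
    with planted ground truth so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
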