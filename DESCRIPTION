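Package: crisprmine
Title: Mining and Characterization of Bacterial CRISPR-Cas Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for mining CRISPR-Cas systems in
    bacterial genome assemblies: de novo detection of repeat-spacer arrays,
    ORF calling and Cas-gene identification in flanking windows, rule-based
    type/subtype classification, spacer-to-protospacer homology search with
    PAM inference from protospacer flanks, anti-repeat tracrRNA prediction
    with crRNA and crRNA:tracrRNA duplex structure models, spacer-content
    strain genotyping, and neighbor-joining Cas-protein phylogenies. A
    truth-tracked simulator generates synthetic genomes, invader databases
    and strain lineages so every stage can be validated against planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn
Config/testthat/edition: 3
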