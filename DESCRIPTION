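Package: nanobar
Title: Field DNA Barcoding from Noisy Long-Read Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning multiplexed, noisy long-read (nanopore-style)
    amplicon sequencing runs into polished DNA barcode consensus sequences.
    Provides barcode demultiplexing by semi-global edit-distance search,
    adapter-only read detection, quality and length filtering on the
    error-rate-averaged phred scale, de novo consensus building by overlap
    clustering and center-star column majority, reference-guided pileup
    consensus, iterative read-backed polishing with homopolymer run-length
    voting, primer trimming, alignment-based accuracy evaluation against a
    truth (Sanger) sequence, coverage-subsampling experiments, and a
    deterministic read simulator with an indel-dominated, homopolymer-biased
    error model for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
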