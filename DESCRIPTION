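Package: cfpeakr
Title: Peak Calling and Annotation of Cell-Free RNA Fragmentomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing UMI-tagged cell-free RNA fragment data from
    plasma. Deduplicates fragments by coordinates, CIGAR and unique molecular
    identifier with one-mismatch collapsing and UMI-saturation correction,
    calls strand-specific RNA peaks against a plasma-DNA baseline with a
    local-lambda Poisson model, annotates peaks against RNA-binding-protein
    sites, repeats and gene features with a reciprocal overlap score, tests
    tandem-repeat strand bias with an Empirical Bayes beta-binomial model and
    Bayes factors, assesses RBP-site and secondary-structure enrichment with
    matched-size random-peak nulls, and classifies full-length excised intron
    RNAs. Includes a synthetic-data generator that plants peaks, strand-biased
    repeats and GU..AG introns with a machine-readable truth table so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    Rcpp,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
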