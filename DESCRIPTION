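Package: srtmap
Title: Transposon Insertion-Site Profiling from Self-Reporting Junction Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide profiling of piggyBac-superfamily transposon
    insertions from junction sequencing reads. Implements anchored trimming of
    the transposon-derived read prefix, mismatch-tolerant seed-and-extend
    placement on a reference, canonical TTAA insertion-site calling with
    target-site-duplication validation and peaks-per-million normalization,
    junction sequence-preference profiles (position frequency matrices with
    per-position information content), TTAA-normalized genomic-feature
    annotation with chi-square comparison of insertion profiles, per-chromosome
    insertion fractions, scanners for repeated transposon-end motifs, imperfect
    palindromes and minimal casein kinase II phosphorylation motifs, and a
    synthetic-data generator that emulates self-reporting transposon libraries
    so every stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    methods,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
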