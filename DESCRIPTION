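Package: methylhet
Title: DNA Methylation Heterogeneity Metrics from Bisulfite Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies inter- and intratumor DNA methylation heterogeneity
    from whole-genome bisulfite sequencing reads. Converts bisulfite
    alignments (or plain-text epiread tables) into per-read CpG methylation
    state vectors, computes read-level heterogeneity statistics (proportion
    of discordant reads, epiallele entropy, epipolymorphism) over 4-CpG
    loci with configurable coverage filters, summarises methylomes (global
    methylation, tile methylation, coefficient of variation across tiles,
    metagene profiles), and associates heterogeneity with clinical
    structure through rank-based group tests, Kaplan-Meier estimation and
    the log-rank test. A fully specified synthetic bisulfite-read generator
    with closed-form metric oracles makes every pipeline stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
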