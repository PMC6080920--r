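Package: mammomics
Title: Integrative Chromatin, Methylome, Transcriptome and Proteome
    Analysis of Mammary Epithelial Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating DNA methylation, open-chromatin,
    RNA and protein profiles of two cell populations (here, basal and
    luminal mammary epithelial cells). Implements differential
    methylation calling from bisulfite count tables with permutation
    tests for feature enrichment, lineage-restricted open-chromatin
    peak classification and gene assignment, position-weight-matrix
    motif scanning with hypergeometric enrichment, label-free
    proteomics abundance harmonization (LFQ with median-adjusted iBAQ
    fallback), per-gene ternary relationship-state classification with
    contingency log-odds association statistics, and single-hit
    Poisson limiting-dilution estimation of stem-cell frequency with
    profile-likelihood confidence intervals. A seeded synthetic-data
    generator reproduces the structure of all input layers with
    recorded ground truth so the full pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
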