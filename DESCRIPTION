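Package: regmapr
Title: Regulatory Maps from TF Motifs, Chromatin Accessibility and Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds genome-wide regulatory maps by combining transcription
    factor (TF) binding motifs, chromatin accessibility and a gene
    expression atlas.  Provides an HMM-based window motif scorer with
    maximum-likelihood site density (Stubb-style), phylogenetically
    weighted multi-species score averaging, top-fraction accessibility
    masking, hypergeometric TF-to-expression-domain association discovery
    across three regulatory-region definitions, and linear
    enhancer-activity models that assign expression domains to open
    chromatin regions.  A synthetic-world generator with planted ground
    truth exercises every stage of the pipeline offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
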