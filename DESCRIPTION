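Package: ptiseq
Title: Time-Course Transcriptome Analysis of Pattern-Triggered Immunity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for time-series RNA-seq analysis of plant
    pattern-triggered immunity (PTI): negative-binomial differential
    expression against a baseline time point with TMM normalization and
    Benjamini-Hochberg adjustment, z-scaled trajectory clustering by
    k-means with gap-statistic assessment of the cluster number, marker
    gene selection, strand-aware 1-kb promoter extraction and degenerate
    cis-regulatory element scanning, and hypergeometric
    over-representation of GO terms, transcription-factor families and
    promoter motifs within expression clusters. Ships a synthetic-data
    generator with planted trajectory archetypes, promoter motifs and
    annotation enrichments so every stage of the pipeline can be
    exercised and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    edgeR,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
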