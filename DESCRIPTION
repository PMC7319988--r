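Package: epicat
Title: Discovery of Epigenetically Suppressed Cryptic Transcription Start
    Sites from CAGE Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide transcription
    start site (TSS) analysis from CAGE 5'-end count data. Per-base CTSS
    tracks are normalized to tags per million, grouped into tag clusters by
    density-stability (paraclu-style) clustering, merged into cross-sample
    consensus clusters, classified against a genome annotation with a strict
    feature precedence, and tested for differential initiation between wild
    type and epigenetic mutants with a self-contained negative-binomial Wald
    test. Non-annotated TSSs activated de novo in mutant backgrounds are
    called EPICATs (epigenetically induced consensus tag clusters).
    Downstream statistics cover promoter shape, positional motif
    architecture, transcription directionality, cytosine methylation
    windows, transposable-element family enrichment, and the impact of
    cryptic TSS activation on neighboring regular TSSs. A seeded synthetic
    data generator provides multi-genotype, multi-replicate CTSS tracks
    with planted regular and cryptic TSSs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
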