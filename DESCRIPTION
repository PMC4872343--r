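Package: stepomics
Title: Integrative Transcriptome-Epigenome Analysis of Stepwise Cell Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-stage isogenic cell-transformation
    designs: differential expression calling with Welch's unequal-variance
    t-test and fold-change gates, classification of differentially expressed
    genes into seven co-expression pathways, quantile and z-score
    normalization of binned ChIP-seq signal, promoter chromatin-state
    classification from five marks (H3K4me3, H3K9ac, H3K27ac, RNA Pol II,
    H3K27me3) into seven states, chromatin-state transition clustering across
    stages, hypergeometric association of transcription-factor regulons with
    co-expression pathways, Pearson-residual integration of chromatin-state
    clusters with pathways, and assembly plus topological hub/bottleneck
    reduction (MNC, DMNC, BottleNeck) of a multi-provenance gene regulatory
    network. Includes a synthetic-data generator with planted ground truth
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
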