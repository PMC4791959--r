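Package: medipchip
Title: MeDIP-Chip Differential Methylation Calling and Transcriptome Integration
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of two-channel MeDIP tiling-array experiments
    on promoter/CpG-island arrays: per-channel background correction and
    quantile normalization, Tukey-biweight-centred log2 IP/input ratios,
    sliding-window Kolmogorov-Smirnov probe scoring, threshold-based calling
    of differentially methylated regions (DMRs) from runs of consecutive
    probes, TSS-anchored genomic classification of DMRs, RMA-style expression
    summarisation with fold-change calling, methylome-transcriptome quadrant
    integration, and McrBC-digestion qPCR validation arithmetic. Includes a
    deterministic synthetic-data generator with planted methylation and
    expression changes so every stage can be tested against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
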