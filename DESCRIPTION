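Package: chromexpr
Title: Integration of Chromatin Signal and Gene Expression Fold Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating histone-modification or RNA-polymerase-II
    occupancy data (ChIP-seq / CUT&Tag peak calls and coverage tracks) with
    gene-level differential expression. Partitions the genome into
    promoter/5'UTR, gene-body and distal-intergenic classes, builds consensus
    peaks across conditions, normalizes counts by median-of-ratios size
    factors, computes per-peak and per-gene (summed and region-averaged)
    log2 fold changes, scaled metagene profiles, per-sample Z-scores and
    differential-expression filters and signatures, and reports
    region-stratified Pearson correlations, quadrant proportions and
    gene-set overlap enrichment. Includes a synthetic-data generator with
    planted region-specific correlation structure for end-to-end validation,
    and a configurable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
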