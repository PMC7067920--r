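Package: dmrshare
Title: Windowed RRBS Differential Methylation and Cross-Tissue DMR Sharing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for age-related differential-methylation
    analysis of reduced-representation bisulfite sequencing (RRBS) count data.
    Reads Bismark-style per-CpG coverage files, filters sites by coverage,
    aggregates counts into fixed-width non-overlapping genomic windows, and
    tests each window for differential methylation between groups with a
    binomial logistic-regression likelihood-ratio test, a per-window
    overdispersion correction, and SLIM (sliding linear model) q-values.
    Called DMRs are annotated against gene models (promoter, exon, intron,
    nearest gene), DMRs shared across two tissues in the same direction are
    identified, and the significance of the shared count is assessed with a
    permutation null. Includes delta-delta-Ct qPCR quantification and a
    synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
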