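Package: chromprofiler
Title: Spike-In Normalized ChIP-Seq Coverage, Metagene and Exon/Intron
    Enrichment Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of histone-mark ChIP-seq signal around gene
    models: RPM and exogenous spike-in normalized coverage tracks built from
    5'-anchored reads extended to a fixed fragment length; TSS-to-TES scaled
    metagene profiles on a 100/300/100 bin scheme with a 5'/3' body-skew
    summary; pooled and per-transcript exon versus intron enrichment scores;
    priority-based assignment of peaks to genomic feature categories; and
    expression-stratified gene-body signal summaries driven by TPM cutoffs and
    rMATS-style differential-splicing tables. A synthetic-data module generates
    annotations, coverage with known exon:intron ratio and positional gradient,
    expression tables and splicing event tables with ground truth, so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    rlang,
    tibble,
    dplyr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
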