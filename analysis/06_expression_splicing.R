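#!/usr/bin/env Rscript
# Link the mark to expression and splicing: stratify genes by TPM (coding:
# low 0<TPM<=2, high TPM>=4; lncRNA: low 0<TPM<=0.1, high TPM>=0.5),
# summarize gene-body signal per stratum as Tukey boxplot statistics, and
# compare exon/intron enrichment between genes whose splicing goes up vs
# down (rMATS-format events, FDR <= 0.05).

suppressMessages(library(chromprofiler))

dat <- "results/data"
res <- "results"
truth <- jsonlite::read_json(file.path(dat, "ground_truth.json"))
sizes <- unlist(truth$chrom_sizes)
ann <- read_gtf(file.path(dat, "annotation.gtf"), chrom_sizes = sizes)
tx <- select_exon_transcripts(ann)
expr <- read_expression_table(file.path(dat, "expression.tsv"))
events <- read_rmats_events(list.files(file.path(dat, "rmats"),
                                       full.names = TRUE))
sets <- splice_event_gene_sets(filter_significant(events))
message(length(sets$Up), " genes with increased and ", length(sets$Down),
        " with decreased splicing")

for (nm in c("canonical", "noncanonical")) {
  tr <- read_bedgraph(file.path(dat, paste0(nm, "_spikein.bedgraph")),
                      sizes, tag = "spikein")
  gbs <- gene_body_signal(tr, ann$genes)

  rows <- list()
  for (bt in c("protein_coding", "lncRNA")) {
    s <- stratify_by_expression(expr, bt)
    for (lvl in c("low", "high")) {
      x <- gbs$mean_signal[gbs$gene_id %in% s[[lvl]]]
      if (length(x) == 0) next
      b <- boxplot_summary(x)
      rows[[paste(bt, lvl)]] <- data.frame(
        biotype = bt, stratum = lvl, n = b$n, median = b$median,
        q1 = b$q1, q3 = b$q3, whisker_low = b$whisker_low,
        whisker_high = b$whisker_high, n_outliers = length(b$outliers))
    }
  }
  strata <- do.call(rbind, rows)
  write.table(strata, file.path(res, paste0("expression_strata_", nm,
                                            ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hi <- strata$median[strata$biotype == "protein_coding" &
                        strata$stratum == "high"]
  lo <- strata$median[strata$biotype == "protein_coding" &
                        strata$stratum == "low"]
  message(sprintf("%s: coding gene-body median %.3f (high) vs %.3f (low)",
                  nm, hi, lo))

  sc <- per_transcript_enrichment(tr, ann, tx$transcript_id)
  agg <- aggregate_enrichment(sc, list(Up = sets$Up, Down = sets$Down,
                                       All = unique(sc$gene_id)))
  write.table(agg, file.path(res, paste0("splicing_enrichment_", nm,
                                         ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: enrichment medians Up %.2f / Down %.2f / All %.2f",
                  nm, agg$median[agg$set == "Up"],
                  agg$median[agg$set == "Down"],
                  agg$median[agg$set == "All"]))
}
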