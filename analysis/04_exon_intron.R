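#!/usr/bin/env Rscript
# Exon vs intron signal: one longest transcript per protein-coding gene,
# overlapping transcripts removed (strand-ignored). Two estimators: the
# pooled average (total signal over total length, exons vs introns) and the
# per-transcript enrichment score (mean exon / mean intron signal).

suppressMessages(library(chromprofiler))

dat <- "results/data"
res <- "results"
truth <- jsonlite::read_json(file.path(dat, "ground_truth.json"))
sizes <- unlist(truth$chrom_sizes)
ann <- read_gtf(file.path(dat, "annotation.gtf"), chrom_sizes = sizes)
tx <- select_exon_transcripts(ann)
message(nrow(tx), " transcripts retained for exon/intron scoring")
write_bed6(tx, file.path(res, "selected_transcripts.bed"),
           name_col = "transcript_id")

glob <- list()
for (nm in c("canonical", "noncanonical")) {
  tr <- read_bedgraph(file.path(dat, paste0(nm, "_spikein.bedgraph")),
                      sizes, tag = "spikein")
  g <- global_exon_intron_signal(tr, ann, tx$transcript_id)
  glob[[nm]] <- g
  message(sprintf("%s: avg exon %.3f, avg intron %.3f, ratio %.3f",
                  nm, g$avg_exon, g$avg_intron, g$ratio))
  sc <- per_transcript_enrichment(tr, ann, tx$transcript_id)
  message(sprintf("  per-transcript median score %.3f (%d defined, %d excluded)",
                  median(sc$score[sc$defined]), attr(sc, "n_defined"),
                  attr(sc, "n_excluded")))
  write.table(sc, file.path(res, paste0("enrichment_scores_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(
  data.frame(condition = names(glob),
             avg_exon = sapply(glob, `[[`, "avg_exon"),
             avg_intron = sapply(glob, `[[`, "avg_intron"),
             ratio = sapply(glob, `[[`, "ratio")),
  file.path(res, "global_exon_intron.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
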