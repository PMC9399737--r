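#!/usr/bin/env Rscript
# Simulate the study inputs: a synthetic genome annotation plus two ChIP-seq
# conditions with known ground truth. The "canonical" condition has strong
# exon enrichment (rho = 3) and a 3'-shifted gradient, as expected for a
# co-transcriptionally deposited mark; the "noncanonical" condition has
# weakened exon preference (rho = 1.5) and a 5'-shifted gradient. Expression
# and differential-splicing tables are generated alongside.

suppressMessages(library(chromprofiler))

seed <- 2026
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gen <- generate_annotation(synth_genome_spec(seed = seed))
ann <- gen$annotation
write_gtf(ann, file.path(out, "annotation.gtf"))
message("annotation: ", nrow(ann$genes), " genes / ",
        nrow(ann$transcripts), " transcripts on ",
        length(ann$chrom_sizes), " chromosomes")

expr <- generate_expression(ann, seed = seed + 1)
write.table(expr$expression, file.path(out, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

conditions <- list(
  canonical = signal_spec(rho = 3, gamma = 0.4, base_depth = 30,
                          expr_coupling = 0.3, noise = "poisson",
                          seed = seed + 2),
  noncanonical = signal_spec(rho = 1.5, gamma = -0.4, base_depth = 30,
                             expr_coupling = 0.3, noise = "poisson",
                             seed = seed + 3)
)
summaries <- list()
for (nm in names(conditions)) {
  cov <- generate_coverage(ann, conditions[[nm]],
                           expression = expr$expression)
  write_bedgraph(cov$track, file.path(out, paste0(nm, "_raw.bedgraph")))
  summaries[[nm]] <- list(n_primary = cov$summary$n_primary,
                          n_spikein = cov$summary$n_spikein)
  message(nm, ": ", cov$summary$n_primary, " primary / ",
          cov$summary$n_spikein, " spike-in reads")
}
jsonlite::write_json(summaries, file.path(out, "alignment_summaries.json"),
                     auto_unbox = TRUE, pretty = TRUE)

ev <- generate_events(ann, n_up = 40, n_down = 40, n_null = 80,
                      seed = seed + 4)
rmats_paths <- write_rmats_tables(ev$events, file.path(out, "rmats"))
message("wrote ", length(rmats_paths), " rMATS-format event tables")

truth <- list(
  chrom_sizes = as.list(ann$chrom_sizes),
  metagene_eligible =
    gen$truth$genes$gene_id[gen$truth$genes$metagene_eligible],
  selected_transcripts =
    gen$truth$transcripts$transcript_id[gen$truth$transcripts$selected],
  splicing_up = ev$truth$up, splicing_down = ev$truth$down,
  conditions = lapply(conditions, function(s)
    list(rho = s$rho, gamma = s$gamma, base_depth = s$base_depth))
)
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote inputs and ground truth under ", out)
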