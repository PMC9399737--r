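#!/usr/bin/env Rscript
# Spike-in normalize the raw coverage tracks. The scale factor per condition
# is 1e6 / spike-in-aligned reads, making signal comparable across samples
# with different global mark levels.

suppressMessages(library(chromprofiler))

dat <- "results/data"
truth <- jsonlite::read_json(file.path(dat, "ground_truth.json"))
sizes <- unlist(truth$chrom_sizes)
ann <- read_gtf(file.path(dat, "annotation.gtf"), chrom_sizes = sizes)
summaries <- jsonlite::read_json(file.path(dat, "alignment_summaries.json"))

for (nm in names(summaries)) {
  s <- alignment_summary(summaries[[nm]]$n_primary,
                         summaries[[nm]]$n_spikein)
  f <- compute_factors(s)
  message(sprintf("%s: rpm factor %.4g, spike-in factor %.4g",
                  nm, f$rpm, f$spikein))
  raw <- read_bedgraph(file.path(dat, paste0(nm, "_raw.bedgraph")), sizes)
  norm <- normalize_track(raw, s, "spikein")
  write_bedgraph(norm, file.path(dat, paste0(nm, "_spikein.bedgraph")))
}
message("wrote spike-in normalized tracks under ", dat)
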