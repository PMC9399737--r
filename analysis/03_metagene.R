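#!/usr/bin/env Rscript
# Metagene profiles: protein-coding genes >= 600 bp with no neighbor within
# 2 kb of TSS or TES, each mapped onto 100 upstream + 300 body + 100
# downstream bins, averaged with equal gene weight. The body-skew summary
# quantifies 5' vs 3' placement of the signal.

suppressMessages(library(chromprofiler))

dat <- "results/data"
res <- "results"
truth <- jsonlite::read_json(file.path(dat, "ground_truth.json"))
sizes <- unlist(truth$chrom_sizes)
ann <- read_gtf(file.path(dat, "annotation.gtf"), chrom_sizes = sizes)
genes <- select_metagene_genes(ann)
message(nrow(genes), " genes pass the metagene filters")
write_bed6(genes, file.path(res, "metagene_genes.bed"))

skews <- list()
for (nm in c("canonical", "noncanonical")) {
  tr <- read_bedgraph(file.path(dat, paste0(nm, "_spikein.bedgraph")),
                      sizes, tag = "spikein")
  prof <- metagene_profile(tr, genes)
  write_metagene_tsv(prof, file.path(res, paste0("metagene_", nm, ".tsv")))
  skews[[nm]] <- body_skew(prof)
  message(sprintf("%s: body skew %.3f (%s-heavy)", nm, skews[[nm]],
                  if (skews[[nm]] < 0) "3'" else "5'"))
}
write.table(data.frame(condition = names(skews),
                       body_skew = unlist(skews)),
            file.path(res, "body_skew.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
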