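test_that("GTF coordinates convert to 0-based half-open and back", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t300\t.\t+\t.\tgene_id "G1"; gene_biotype "protein_coding";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t";',
    'chr1\tsrc\texon\t251\t300\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t";'
  ), f)
  ann <- read_gtf(f)
  expect_equal(ann$exons$start, c(100, 250))
  expect_equal(ann$exons$end, c(200, 300))
  expect_equal(ann$genes$start, 100)
  expect_equal(ann$genes$end, 300)

  # round trip preserves all intervals and attributes the package uses
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f2)
  ann2 <- read_gtf(f2, ann$chrom_sizes)
  expect_equal(as.data.frame(ann$genes), as.data.frame(ann2$genes))
  expect_equal(as.data.frame(ann$transcripts), as.data.frame(ann2$transcripts))
  expect_equal(as.data.frame(ann$exons), as.data.frame(ann2$exons))
})

test_that("empty GTF gives an empty annotation without error", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines("# just a comment", f)
  ann <- read_gtf(f)
  expect_equal(nrow(ann$genes), 0)
  expect_equal(nrow(ann$exons), 0)
})

test_that("malformed GTF lines raise errors naming the line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "t";',
    "chr1\tbroken line"
  ), f)
  expect_error(read_gtf(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1";', f2)
  expect_error(read_gtf(f2), "line 1.*transcript_id")
})

test_that("synthetic GTF reloads with the generator's structure", {
  gen <- generate_annotation(small_spec())
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gen$annotation, f)
  ann <- read_gtf(f, gen$annotation$chrom_sizes)
  expect_equal(nrow(ann$genes), nrow(gen$annotation$genes))
  expect_equal(as.data.frame(ann$exons), as.data.frame(gen$annotation$exons))
})

test_that("introns are the gaps between exons; abutting exons give none", {
  ann <- tiny_ann()
  ia <- derive_introns(ann, "A.1")
  expect_equal(nrow(ia), 1)
  expect_equal(ia$start, 10200)
  expect_equal(ia$end, 10400)
  expect_equal(nrow(derive_introns(ann, "L.1")), 0)  # single exon

  # abutting exons: a zero-length gap is not an intron
  ab <- genome_annotation(
    c(chr1 = 1000),
    tibble::tibble(gene_id = "G", chrom = "chr1", start = 0, end = 20,
                   strand = "+", biotype = "protein_coding"),
    tibble::tibble(transcript_id = "G.1", gene_id = "G", chrom = "chr1",
                   start = 0, end = 20, strand = "+"),
    tibble::tibble(transcript_id = c("G.1", "G.1"), gene_id = "G",
                   chrom = "chr1", start = c(0, 10), end = c(10, 20),
                   strand = "+")
  )
  expect_equal(nrow(derive_introns(ab)), 0)
})

test_that("exons and introns tile each transcript span exactly", {
  gen <- generate_annotation(small_spec(seed = 3))
  ann <- gen$annotation
  ins <- derive_introns(ann)
  exl <- tapply(ann$exons$end - ann$exons$start, ann$exons$transcript_id, sum)
  inl <- tapply(ins$end - ins$start, ins$transcript_id, sum)
  for (i in seq_len(nrow(ann$transcripts))) {
    tx <- ann$transcripts[i, ]
    span <- tx$end - tx$start
    tot <- exl[[tx$transcript_id]] +
      (if (tx$transcript_id %in% names(inl)) inl[[tx$transcript_id]] else 0)
    expect_equal(tot, span)
  }
})

test_that("metagene gene selection applies length and isolation filters", {
  mk <- function(starts, ends, biotypes = NULL, len = 1e6) {
    n <- length(starts)
    if (is.null(biotypes)) biotypes <- rep("protein_coding", n)
    ids <- paste0("G", seq_len(n))
    genome_annotation(
      c(chr1 = len),
      tibble::tibble(gene_id = ids, chrom = "chr1", start = starts,
                     end = ends, strand = "+", biotype = biotypes),
      tibble::tibble(transcript_id = paste0(ids, ".1"), gene_id = ids,
                     chrom = "chr1", start = starts, end = ends,
                     strand = "+"),
      tibble::tibble(transcript_id = paste0(ids, ".1"), gene_id = ids,
                     chrom = "chr1", start = starts, end = ends,
                     strand = "+")
    )
  }
  # 10 kb apart: both pass
  expect_equal(select_metagene_genes(mk(c(10000, 21000),
                                        c(11000, 22000)))$gene_id,
               c("G1", "G2"))
  # 1 kb apart: window of each hits the other
  expect_equal(nrow(select_metagene_genes(mk(c(10000, 12000),
                                             c(11000, 13000)))), 0)
  # 599 bp isolated gene excluded, 600 bp included (boundary)
  expect_equal(nrow(select_metagene_genes(mk(10000, 10599))), 0)
  expect_equal(nrow(select_metagene_genes(mk(10000, 10600))), 1)
  # a lncRNA neighbor still breaks isolation but is never itself selected
  sel <- select_metagene_genes(mk(c(10000, 12000), c(11000, 13000),
                                  c("protein_coding", "lncRNA")))
  expect_equal(nrow(sel), 0)
})

test_that("gene selection is order-independent and matches brute force", {
  gen <- generate_annotation(small_spec(seed = 5))
  ann <- gen$annotation
  sel <- select_metagene_genes(ann)
  expect_setequal(sel$gene_id,
                  gen$truth$genes$gene_id[gen$truth$genes$metagene_eligible])

  perm <- ann
  set.seed(1)
  perm$genes <- perm$genes[sample(nrow(perm$genes)), ]
  expect_equal(select_metagene_genes(perm)$gene_id, sel$gene_id)
})

test_that("longest-transcript selection and overlap removal are exact", {
  ann <- tiny_ann()
  sel <- select_exon_transcripts(ann)
  expect_setequal(sel$transcript_id, c("A.1", "B.1"))  # lncRNA excluded

  # a 1 bp overlap removes both members of the pair
  two <- genome_annotation(
    c(chr1 = 1e5),
    tibble::tibble(gene_id = c("X", "Y"), chrom = "chr1",
                   start = c(1000, 4999), end = c(5000, 9000),
                   strand = c("+", "-"),
                   biotype = "protein_coding"),
    tibble::tibble(transcript_id = c("X.1", "Y.1"), gene_id = c("X", "Y"),
                   chrom = "chr1", start = c(1000, 4999),
                   end = c(5000, 9000), strand = c("+", "-")),
    tibble::tibble(transcript_id = c("X.1", "Y.1"), gene_id = c("X", "Y"),
                   chrom = "chr1", start = c(1000, 4999),
                   end = c(5000, 9000), strand = c("+", "-"))
  )
  expect_equal(nrow(select_exon_transcripts(two)), 0)

  # longest isoform wins within a gene
  gen <- generate_annotation(small_spec(seed = 9))
  sel <- select_exon_transcripts(gen$annotation)
  tt <- gen$truth$transcripts
  expect_setequal(sel$transcript_id, tt$transcript_id[tt$selected])

  # invariant: zero pairwise overlaps, verified by all-pairs loop
  if (nrow(sel) > 1) {
    for (i in seq_len(nrow(sel) - 1)) {
      for (j in (i + 1):nrow(sel)) {
        if (sel$chrom[i] != sel$chrom[j]) next
        expect_false(overlaps(sel$start[i], sel$end[i],
                              sel$start[j], sel$end[j]))
      }
    }
  }
})
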