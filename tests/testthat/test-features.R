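empty_genes_tbl <- function() tibble::tibble(
  gene_id = character(), chrom = character(), start = numeric(),
  end = numeric(), strand = character(), biotype = character())
empty_tx_tbl <- function() tibble::tibble(
  transcript_id = character(), gene_id = character(), chrom = character(),
  start = numeric(), end = numeric(), strand = character())
empty_ex_tbl <- function() tibble::tibble(
  transcript_id = character(), gene_id = character(), chrom = character(),
  start = numeric(), end = numeric(), strand = character())

test_that("the feature index partitions UTR, exon, intron and intergenic space", {
  ann <- tiny_ann()
  idx <- build_feature_index(ann)

  # per-base oracle on chr1: categories as logical masks
  n <- ann$chrom_sizes[["chr1"]]
  in_gene <- logical(n); in_exon <- logical(n); in_utr <- logical(n)
  for (i in which(ann$genes$chrom == "chr1")) {
    in_gene[(ann$genes$start[i] + 1):ann$genes$end[i]] <- TRUE
  }
  for (i in which(ann$exons$chrom == "chr1")) {
    in_exon[(ann$exons$start[i] + 1):ann$exons$end[i]] <- TRUE
  }
  for (i in which(ann$utrs$chrom == "chr1")) {
    in_utr[(ann$utrs$start[i] + 1):ann$utrs$end[i]] <- TRUE
  }
  cat_bp <- function(gr, chrom) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    sum(GenomicRanges::width(g))
  }
  expect_equal(cat_bp(idx$Exon, "chr1"), sum(in_exon & !in_utr))
  expect_equal(cat_bp(idx$`5UTR`, "chr1") + cat_bp(idx$`3UTR`, "chr1"),
               sum(in_utr))
  expect_equal(cat_bp(idx$Intergenic, "chr1"), sum(!in_gene))
  expect_equal(cat_bp(idx$Intron, "chr1"), sum(in_gene & !in_exon))

  # without UTR features those categories are empty
  ann2 <- tiny_ann(); ann2$utrs <- ann2$utrs[0, ]
  idx2 <- build_feature_index(ann2)
  expect_equal(length(idx2$`5UTR`), 0)
  expect_gt(cat_bp(idx2$Exon, "chr1"), cat_bp(idx$Exon, "chr1"))

  # empty annotation: everything intergenic
  e <- genome_annotation(c(chr1 = 1000), empty_genes_tbl(),
                         empty_tx_tbl(), empty_ex_tbl())
  idx3 <- build_feature_index(e)
  expect_equal(sum(GenomicRanges::width(idx3$Intergenic)), 1000)
})

test_that("peaks get the first category in priority order with overlap", {
  ann <- tiny_ann()
  idx <- build_feature_index(ann)

  # wholly inside B's first intron [30400, 30700)
  p1 <- tibble::tibble(chrom = "chr1", start = 30450, end = 30600)
  expect_equal(annotate_peaks(p1, idx)$category, "Intron")

  # straddling the gene end into intergenic space: Intergenic is first
  p2 <- tibble::tibble(chrom = "chr1", start = 31900, end = 32100)
  expect_equal(annotate_peaks(p2, idx)$category, "Intergenic")

  # exon + intron only (inside B, no UTRs there): Exon precedes Intron
  p3 <- tibble::tibble(chrom = "chr1", start = 30350, end = 30500)
  expect_equal(annotate_peaks(p3, idx)$category, "Exon")

  # a different priority reorders only multi-category peaks
  alt <- c("Intron", "Exon", "3UTR", "5UTR", "Intergenic")
  expect_equal(annotate_peaks(p3, idx, priority = alt)$category, "Intron")
  expect_equal(annotate_peaks(p1, idx, priority = alt)$category, "Intron")

  expect_error(annotate_peaks(tibble::tibble(chrom = "chrZ", start = 0,
                                             end = 10), idx),
               "unknown chromosome")
  expect_error(annotate_peaks(p1, idx, priority = c("Exon", "Intron")),
               "permutation")
})

test_that("feature distributions match hand counts and sum to one", {
  ann <- tiny_ann()
  idx <- build_feature_index(ann)
  # 10 crafted peaks: 3 intronic (B introns), 2 exonic (B exons), 2
  # intergenic spillovers, 1 pure intergenic, 1 in A's 5'UTR, 1 in A's 3'UTR
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(30450, 30500, 31100, 30350, 31600, 31990, 29990, 20000,
              10000, 10560),
    end = c(30600, 30650, 31400, 30390, 31700, 32050, 30050, 20200,
            10040, 10590)
  )
  dist <- feature_distribution(peaks, idx)
  expect_equal(sum(dist$fraction), 1)
  expect_equal(dist$count[dist$category == "Intron"], 3L)
  expect_equal(dist$count[dist$category == "Exon"], 2L)
  expect_equal(dist$count[dist$category == "Intergenic"], 3L)
  expect_equal(dist$count[dist$category == "5UTR"], 1L)
  expect_equal(dist$count[dist$category == "3UTR"], 1L)

  # all-intronic input
  d2 <- feature_distribution(peaks[1:3, ], idx)
  expect_equal(d2$fraction[d2$category == "Intron"], 1)
  expect_error(feature_distribution(peaks[0, ], idx), "empty")
})

test_that("peak overlap fraction is asymmetric and brute-force checkable", {
  a <- tibble::tibble(chrom = "chr1", start = c(0, 100, 200, 300),
                      end = c(50, 150, 250, 350))
  expect_equal(peak_overlap_fraction(a, a), 1)
  b_far <- tibble::tibble(chrom = "chr1", start = 1000, end = 1100)
  expect_equal(peak_overlap_fraction(a, b_far), 0)
  # 3 of 4 a-peaks touch b
  b <- tibble::tibble(chrom = "chr1", start = c(40, 140, 240),
                      end = c(60, 160, 260))
  brute <- mean(vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      overlaps(a$start[i], a$end[i], b$start[j], b$end[j])
    }, logical(1)))
  }, numeric(1)))
  expect_equal(peak_overlap_fraction(a, b), 0.75)
  expect_equal(peak_overlap_fraction(a, b), brute)
  # monotone nondecreasing as b grows
  expect_gte(peak_overlap_fraction(a, dplyr::bind_rows(b, a)),
             peak_overlap_fraction(a, b))
  expect_error(peak_overlap_fraction(a[0, ], b), "nonempty")
})

test_that("BED round trip preserves peak intervals", {
  p <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(10, 20),
                      end = c(110, 220), name = c("p1", "p2"),
                      score = c(5, 7), strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(p, f)
  back <- read_bed(f)
  expect_equal(back$start, p$start)
  expect_equal(back$end, p$end)
  expect_equal(back$name, p$name)
})
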