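cs <- c(chr1 = 100000)

test_that("normalization factors are 1e6 over the aligned-read counts", {
  expect_equal(compute_factors(alignment_summary(1e6, 5e5))$rpm, 1)
  expect_equal(compute_factors(alignment_summary(2e6, 5e5))$rpm, 0.5)
  expect_equal(compute_factors(alignment_summary(2e6, 5e5))$spikein, 2)
  expect_error(compute_factors(alignment_summary(0, 10), which = "rpm"),
               "primary")
  expect_error(compute_factors(alignment_summary(10, 0), which = "spikein"),
               "spike-in")
})

test_that("reads extend from their 5' end in strand direction", {
  r <- tibble::tibble(chrom = "chr1", pos = 0, strand = "+")
  t <- reads_to_coverage(r, cs, ext = 150, mode = "raw")
  expect_equal(mean_signal(t, "chr1", 0, 150), 1)
  expect_equal(mean_signal(t, "chr1", 150, 300), 0)

  # minus read with 5' end at 200 covers [50, 200)
  rm <- tibble::tibble(chrom = "chr1", pos = 200, strand = "-")
  tm <- reads_to_coverage(rm, cs, ext = 150, mode = "raw")
  expect_equal(mean_signal(tm, "chr1", 50, 200), 1)
  expect_equal(mean_signal(tm, "chr1", 0, 50), 0)
  expect_equal(mean_signal(tm, "chr1", 200, 300), 0)

  # two identical reads at RPM with 2 aligned reads give 1e6
  r2 <- r[c(1, 1), ]
  t2 <- reads_to_coverage(r2, cs, ext = 150, mode = "rpm",
                          summary = alignment_summary(2))
  expect_equal(mean_signal(t2, "chr1", 0, 150), 1e6)

  # extension clips at chromosome bounds instead of erroring
  redge <- tibble::tibble(chrom = "chr1", pos = 99990, strand = "+")
  te <- reads_to_coverage(redge, cs, ext = 150, mode = "raw")
  expect_equal(sum_signal(te, "chr1", 99900, 100000), 10)

  expect_error(reads_to_coverage(tibble::tibble(chrom = "chr1", pos = 1e6,
                                                strand = "+"), cs),
               "outside")
  expect_error(reads_to_coverage(tibble::tibble(chrom = "chrX", pos = 1,
                                                strand = "+"), cs),
               "unknown")
})

test_that("raw coverage mass equals reads x ext minus clipped bases", {
  set.seed(42)
  n <- 200
  r <- tibble::tibble(chrom = "chr1",
                      pos = sample(0:(cs[["chr1"]] - 1), n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE))
  t <- reads_to_coverage(r, cs, ext = 150, mode = "raw")
  clipped <- sum(pmax(0, ifelse(r$strand == "-", 150 - r$pos,
                                r$pos + 150 - cs[["chr1"]])))
  expect_equal(track_total(t), n * 150 - clipped)
})

test_that("mean_signal is a length-weighted mean, stable under subdivision", {
  t <- flat_track(cs, value = 3.7)
  expect_equal(mean_signal(t, "chr1", 123, 4567), 3.7)

  r <- tibble::tibble(chrom = "chr1", pos = 0, strand = "+")
  t2 <- reads_to_coverage(r[c(1, 1), ], cs, ext = 50, mode = "raw")
  expect_equal(mean_signal(t2, "chr1", 0, 100), 1)  # 2 on [0,50), 0 after
  expect_equal(mean_signal(t2, "chr1", 5000, 6000), 0)
  expect_error(mean_signal(t2, "chr1", 10, 10), "empty")

  # partition invariance
  set.seed(7)
  cuts <- sort(sample(1:99, 5))
  bounds <- c(0, cuts, 100)
  parts <- mean_signal(t2, "chr1", utils::head(bounds, -1),
                       utils::tail(bounds, -1))
  w <- diff(bounds)
  expect_equal(sum(parts * w) / sum(w), mean_signal(t2, "chr1", 0, 100))

  # agreement with the per-base oracle
  expect_equal(mean_signal(t2, "chr1", 13, 177),
               naive_mean(t2, "chr1", 13, 177))
})

test_that("ratio tracks apply the pseudocount symmetrically", {
  a <- flat_track(cs, value = 4)
  b <- flat_track(cs, value = 4)
  expect_equal(mean_signal(ratio_track(a, b), "chr1", 0, 100), 1)

  # num = 2 * den approaches 2 as eps -> 0
  d <- flat_track(cs, value = 3)
  n2 <- flat_track(cs, value = 6)
  expect_equal(mean_signal(ratio_track(n2, d, eps = 1e-6), "chr1", 0, 100), 2,
               tolerance = 1e-6)
  # 0/0 = eps/eps = 1
  z <- flat_track(cs, value = 0)
  expect_equal(mean_signal(ratio_track(z, z), "chr1", 0, 100), 1)
  expect_error(ratio_track(a, b, eps = 0), "eps")
  expect_error(ratio_track(a, flat_track(c(chr2 = 10))), "universe")
})

test_that("bedGraph round-trips losslessly and rejects overlaps", {
  gen <- generate_coverage(generate_annotation(small_spec())$annotation,
                           signal_spec(noise = "poisson", seed = 2))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(gen$track, f)
  back <- read_bedgraph(f, gen$track$chrom_sizes)
  expect_identical(lapply(gen$track$cov, as.numeric),
                   lapply(back$cov, as.numeric))

  # a simple line maps to the right run
  f2 <- withr::local_tempfile()
  writeLines("chr1\t0\t150\t1.0", f2)
  t2 <- read_bedgraph(f2, cs)
  expect_equal(sum_signal(t2, "chr1", 0, 200), 150)

  # unsorted input equals its sorted counterpart
  f3 <- withr::local_tempfile(); f4 <- withr::local_tempfile()
  writeLines(c("chr1\t500\t600\t2", "chr1\t0\t100\t1"), f3)
  writeLines(c("chr1\t0\t100\t1", "chr1\t500\t600\t2"), f4)
  expect_identical(lapply(read_bedgraph(f3, cs)$cov, as.numeric),
                   lapply(read_bedgraph(f4, cs)$cov, as.numeric))

  f5 <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), f5)
  expect_error(read_bedgraph(f5, cs), "overlap")
})

test_that("bigWig round-trips the run-length values", {
  t <- reads_to_coverage(
    tibble::tibble(chrom = "chr1", pos = c(100, 300, 350), strand = "+"),
    cs, ext = 150, mode = "raw")
  f <- withr::local_tempfile(fileext = ".bw")
  write_bigwig(t, f)
  back <- read_bigwig(f, cs)
  expect_equal(lapply(t$cov, as.numeric), lapply(back$cov, as.numeric))
})

test_that("spike-in normalization is invariant under c-fold duplication", {
  set.seed(99)
  r <- tibble::tibble(chrom = "chr1",
                      pos = sample(0:99000, 57, replace = TRUE),
                      strand = sample(c("+", "-"), 57, replace = TRUE))
  s <- alignment_summary(n_primary = 57, n_spikein = 13)
  t1 <- reads_to_coverage(r, cs, mode = "spikein", summary = s)
  for (c_fold in c(2L, 3L, 7L)) {
    rc <- r[rep(seq_len(nrow(r)), each = c_fold), ]
    sc <- alignment_summary(57 * c_fold, 13 * c_fold)
    tc <- reads_to_coverage(rc, cs, mode = "spikein", summary = sc)
    expect_identical(t1$cov, tc$cov)  # exact, not approximate
  }
})
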