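# Hand-built fixtures and independent oracles shared across the suite.

# A small annotation with known structure: two multi-exon coding genes on
# opposite strands, a single-exon lncRNA, and UTRs on gene A.
tiny_ann <- function() {
  cs <- c(chr1 = 50000, chr2 = 30000)
  genes <- tibble::tibble(
    gene_id = c("A", "B", "L"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 30000, 5000),
    end = c(10600, 32000, 5600),
    strand = c("+", "-", "+"),
    biotype = c("protein_coding", "protein_coding", "lncRNA")
  )
  transcripts <- tibble::tibble(
    transcript_id = c("A.1", "B.1", "L.1"),
    gene_id = c("A", "B", "L"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 30000, 5000),
    end = c(10600, 32000, 5600),
    strand = c("+", "-", "+")
  )
  exons <- tibble::tibble(
    transcript_id = c("A.1", "A.1", "B.1", "B.1", "B.1", "L.1"),
    gene_id = c("A", "A", "B", "B", "B", "L"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10000, 10400, 30000, 30700, 31500, 5000),
    end = c(10200, 10600, 30400, 31000, 32000, 5600),
    strand = c("+", "+", "-", "-", "-", "+")
  )
  utrs <- tibble::tibble(
    transcript_id = c("A.1", "A.1"),
    chrom = c("chr1", "chr1"),
    start = c(10000, 10550),
    end = c(10050, 10600),
    strand = c("+", "+"),
    type = c("five_prime_utr", "three_prime_utr")
  )
  genome_annotation(cs, genes, transcripts, exons, utrs)
}

# compact generator settings for fast tests
small_spec <- function(seed = 11, n_genes = 30, ...) {
  synth_genome_spec(n_chroms = 1, chrom_len = 6e5, n_genes = n_genes,
                    seed = seed, ...)
}

# per-base oracle for interval means, bypassing Views/Rle aggregation
naive_mean <- function(track, chrom, start, end) {
  v <- as.numeric(track$cov[[chrom]])
  mean(v[(start + 1):end])
}

naive_sum <- function(track, chrom, start, end) {
  v <- as.numeric(track$cov[[chrom]])
  sum(v[(start + 1):end])
}

# brute-force linear-interpolation quantile of sorted order statistics,
# independent of stats::quantile
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# scale every value of a track by a constant
scale_track <- function(track, c) {
  coverage_track(lapply(track$cov, function(r) r * c), track$chrom_sizes,
                 tag = track$tag)
}

# brute-force pairwise interval overlap (0-based half-open)
overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
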