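FEATURE_CATEGORIES <- c("Intergenic", "5UTR", "3UTR", "Exon", "Intron")

ivs_to_granges <- function(df, chrom_sizes = NULL) {
  if (is.null(df) || nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

#' Build the genomic feature index for peak annotation
#'
#' Partitions the annotated genome into five categories: `5UTR` and `3UTR`
#' (explicit UTR features, when present), `Exon` (exonic bases not in a UTR),
#' `Intron` (gaps between consecutive exons of a transcript) and `Intergenic`
#' (the complement of all gene spans). Categories from different genes may
#' overlap genomically; the priority order resolves them per peak.
#'
#' @param ann a [genome_annotation].
#' @return list of reduced `GRanges`, one per category, plus `chrom_sizes`.
#' @export
build_feature_index <- function(ann) {
  cs <- ann$chrom_sizes
  whole <- GenomicRanges::GRanges(names(cs), IRanges::IRanges(1, cs))
  spans <- GenomicRanges::reduce(ivs_to_granges(ann$genes),
                                 ignore.strand = TRUE)
  intergenic <- GenomicRanges::setdiff(whole, spans, ignore.strand = TRUE)

  utr5 <- GenomicRanges::reduce(
    ivs_to_granges(ann$utrs[ann$utrs$type == "five_prime_utr", ]),
    ignore.strand = TRUE)
  utr3 <- GenomicRanges::reduce(
    ivs_to_granges(ann$utrs[ann$utrs$type == "three_prime_utr", ]),
    ignore.strand = TRUE)
  exonic <- GenomicRanges::reduce(ivs_to_granges(ann$exons),
                                  ignore.strand = TRUE)
  utr_all <- GenomicRanges::reduce(c(utr5, utr3), ignore.strand = TRUE)
  exon <- GenomicRanges::setdiff(exonic, utr_all, ignore.strand = TRUE)
  intron <- GenomicRanges::reduce(ivs_to_granges(derive_introns(ann)),
                                  ignore.strand = TRUE)

  list(Intergenic = intergenic, `5UTR` = utr5, `3UTR` = utr3,
       Exon = exon, Intron = intron, chrom_sizes = cs)
}

peak_granges <- function(peaks, chrom_sizes) {
  peaks <- tibble::as_tibble(peaks)
  if (!all(peaks$chrom %in% names(chrom_sizes))) {
    stop("peak on unknown chromosome: ",
         paste(setdiff(unique(peaks$chrom), names(chrom_sizes)),
               collapse = ", "))
  }
  ivs_to_granges(peaks)
}

#' Assign peaks to feature categories by priority
#'
#' Computes, for every peak, the overlap in bp with each feature category and
#' assigns the first category in `priority` order that has nonzero overlap.
#' The default priority is Intergenic, 5UTR, 3UTR, Exon, Intron — applied
#' literally, so a peak spilling a single base into intergenic space is called
#' Intergenic.
#'
#' @param peaks tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param index feature index from [build_feature_index].
#' @param priority permutation of the five category names.
#' @return the peak tibble with a `category` column and per-category
#'   `overlap_*` bp columns.
#' @export
annotate_peaks <- function(peaks, index, priority = FEATURE_CATEGORIES) {
  if (!setequal(priority, FEATURE_CATEGORIES) ||
      length(priority) != length(FEATURE_CATEGORIES)) {
    stop("priority must be a permutation of: ",
         paste(FEATURE_CATEGORIES, collapse = ", "))
  }
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0) stop("empty peak list")
  gr <- peak_granges(peaks, index$chrom_sizes)

  ov <- sapply(FEATURE_CATEGORIES, function(cat) {
    feat <- index[[cat]]
    out <- numeric(length(gr))
    if (length(feat) == 0) return(out)
    hits <- GenomicRanges::findOverlaps(gr, feat, ignore.strand = TRUE)
    if (length(hits) == 0) return(out)
    w <- GenomicRanges::width(IRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], feat[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  })
  ov <- matrix(ov, nrow = length(gr),
               dimnames = list(NULL, FEATURE_CATEGORIES))
  pick <- apply(ov[, priority, drop = FALSE] > 0, 1, which.max)
  none <- rowSums(ov) == 0
  category <- priority[pick]
  category[none] <- NA_character_
  out <- peaks
  out$category <- category
  for (cat in FEATURE_CATEGORIES) {
    out[[paste0("overlap_", tolower(cat))]] <- ov[, cat]
  }
  out
}

#' Genomic feature distribution of a peak set
#'
#' @param peaks tibble of peaks; must be nonempty.
#' @param index feature index from [build_feature_index].
#' @param priority category priority passed to [annotate_peaks].
#' @return tibble with `category`, `count`, `fraction` (fractions sum to 1);
#'   all five categories are reported, in priority order.
#' @export
feature_distribution <- function(peaks, index,
                                 priority = FEATURE_CATEGORIES) {
  assigned <- annotate_peaks(peaks, index, priority)
  counts <- table(factor(assigned$category, levels = priority))
  tibble::tibble(
    category = names(counts),
    count = as.integer(counts),
    fraction = as.integer(counts) / sum(counts)
  )
}

#' Fraction of peaks in `a` overlapping any peak in `b`
#'
#' Asymmetric: the denominator is `nrow(a)`; a peak counts as overlapping on
#' at least 1 bp of shared span with any member of `b`.
#'
#' @param a,b nonempty peak tibbles (`chrom`, `start`, `end`).
#' @export
peak_overlap_fraction <- function(a, b) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("peak sets must be nonempty")
  ga <- ivs_to_granges(a)
  gb <- ivs_to_granges(b)
  mean(GenomicRanges::countOverlaps(ga, gb, ignore.strand = TRUE) > 0)
}

#' Read a BED file (3+ columns) into a peak tibble
#' @param path BED path; 0-based half-open coordinates are kept as-is.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  tibble::as_tibble(df)
}

#' Write a peak tibble as BED
#' @param peaks tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  cols <- list(peaks$chrom, as.integer(peaks$start), as.integer(peaks$end))
  if (!is.null(peaks$name)) {
    cols <- c(cols, list(peaks$name,
                         if (is.null(peaks$score)) 0L else peaks$score,
                         if (is.null(peaks$strand)) "." else peaks$strand))
  }
  utils::write.table(do.call(data.frame, cols), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
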