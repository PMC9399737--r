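#' Coverage track container
#'
#' A `coverage_track` is a per-chromosome stepwise signal: one run-length
#' encoded vector (`S4Vectors::Rle`) per chromosome, each spanning the full
#' chromosome length, plus a tag recording how the track was normalized
#' (`raw`, `rpm`, `spikein` or `ratio`). Non-ratio tracks are non-negative.
#'
#' @param cov named list of `Rle` vectors, one per chromosome.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param tag normalization tag.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(cov, chrom_sizes,
                           tag = c("raw", "rpm", "spikein", "ratio")) {
  tag <- match.arg(tag)
  stopifnot(is.list(cov), !is.null(names(cov)),
            all(names(cov) %in% names(chrom_sizes)))
  for (chr in names(chrom_sizes)) {
    if (is.null(cov[[chr]])) {
      cov[[chr]] <- S4Vectors::Rle(0, chrom_sizes[[chr]])
    }
    if (length(cov[[chr]]) != chrom_sizes[[chr]]) {
      stop("track for ", chr, " has length ", length(cov[[chr]]),
           ", expected ", chrom_sizes[[chr]])
    }
  }
  if (tag != "ratio") {
    neg <- vapply(cov, function(r) min(S4Vectors::runValue(r)) < 0,
                  logical(1))
    if (any(neg)) stop("negative values in a non-ratio track")
  }
  structure(list(cov = cov[names(chrom_sizes)], chrom_sizes = chrom_sizes,
                 tag = tag),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", x$tag, "): ", length(x$chrom_sizes),
      " chromosome(s), ", format(sum(x$chrom_sizes), big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

#' Constant-valued track over a chromosome set
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param value the constant signal value.
#' @param tag normalization tag for the result.
#' @export
flat_track <- function(chrom_sizes, value = 0, tag = "raw") {
  cov <- lapply(chrom_sizes, function(n) S4Vectors::Rle(value, n))
  coverage_track(cov, chrom_sizes, tag)
}

#' Alignment summary for normalization
#'
#' Read counts aligned to the primary genome and to the exogenous spike-in
#' genome, the two denominators of the normalization factors.
#'
#' @param n_primary reads aligned to the primary genome.
#' @param n_spikein reads aligned to the spike-in genome.
#' @export
alignment_summary <- function(n_primary, n_spikein = NA_real_) {
  stopifnot(is.na(n_primary) || n_primary >= 0,
            is.na(n_spikein) || n_spikein >= 0)
  structure(list(n_primary = n_primary, n_spikein = n_spikein),
            class = "alignment_summary")
}

#' Per-read normalization factors
#'
#' The RPM factor is 1e6 divided by the number of reads aligned to the primary
#' genome; the spike-in factor is 1e6 divided by the number of reads aligned
#' to the spike-in genome.
#'
#' @param s an [alignment_summary].
#' @param which factors to compute; a zero or missing count for a requested
#'   factor is an error naming the genome.
#' @return list with elements `rpm` and/or `spikein`.
#' @export
compute_factors <- function(s, which = c("rpm", "spikein")) {
  which <- match.arg(which, several.ok = TRUE)
  out <- list()
  if ("rpm" %in% which) {
    if (is.na(s$n_primary) || s$n_primary <= 0) {
      stop("RPM factor undefined: no reads aligned to the primary genome")
    }
    out$rpm <- 1e6 / s$n_primary
  }
  if ("spikein" %in% which) {
    if (is.na(s$n_spikein) || s$n_spikein <= 0) {
      stop("spike-in factor undefined: no reads aligned to the spike-in genome")
    }
    out$spikein <- 1e6 / s$n_spikein
  }
  out
}

#' Build a normalized coverage track from 5'-anchored reads
#'
#' Each read contributes an interval of length `ext` starting at its 5' end
#' and extending in the read-strand direction (a minus-strand read with 5' end
#' at p covers `[p - ext, p)`), clipped at chromosome bounds. The pileup depth
#' is scaled by the selected normalization factor; scaling is computed as
#' `depth * 1e6 / n`, one correctly rounded division, so duplicating every
#' read c-fold while scaling the alignment counts by c reproduces the track
#' exactly.
#'
#' @param reads tibble with columns `chrom`, `pos` (0-based 5'-end offset) and
#'   `strand`.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param ext extension length in bp (default 150).
#' @param mode `raw`, `rpm` or `spikein`.
#' @param summary an [alignment_summary]; required for `rpm` / `spikein`.
#' @return A [coverage_track] tagged with `mode`.
#' @export
reads_to_coverage <- function(reads, chrom_sizes, ext = 150,
                              mode = c("raw", "rpm", "spikein"),
                              summary = NULL) {
  mode <- match.arg(mode)
  stopifnot(ext > 0)
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) > 0) {
    if (!all(reads$chrom %in% names(chrom_sizes))) {
      stop("read on unknown chromosome")
    }
    if (any(reads$pos < 0) || any(reads$pos >= chrom_sizes[reads$chrom])) {
      stop("read 5' position outside chromosome bounds")
    }
  }
  start0 <- ifelse(reads$strand == "-", reads$pos - ext, reads$pos)
  end0 <- ifelse(reads$strand == "-", reads$pos, reads$pos + ext)
  start0 <- pmax(start0, 0)
  end0 <- pmin(end0, chrom_sizes[reads$chrom])

  cov <- lapply(names(chrom_sizes), function(chr) {
    i <- which(reads$chrom == chr)
    if (length(i) == 0) return(S4Vectors::Rle(0L, chrom_sizes[[chr]]))
    IRanges::coverage(IRanges::IRanges(start0[i] + 1, end0[i]),
                      width = chrom_sizes[[chr]])
  })
  names(cov) <- names(chrom_sizes)

  if (mode != "raw") {
    f <- compute_factors(summary,
                         which = if (mode == "rpm") "rpm" else "spikein")
    n <- if (mode == "rpm") summary$n_primary else summary$n_spikein
    cov <- lapply(cov, function(r) (r * 1e6) / n)
  }
  coverage_track(cov, chrom_sizes, tag = mode)
}

resolve_intervals <- function(track, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (any(end <= start)) stop("empty interval: need end > start")
  if (!all(chrom %in% names(track$chrom_sizes))) {
    stop("interval on unknown chromosome")
  }
  if (any(start < 0) || any(end > track$chrom_sizes[chrom])) {
    stop("interval outside chromosome bounds")
  }
  list(chrom = chrom, start = start, end = end, n = n)
}

view_stat <- function(track, chrom, start, end, statf) {
  iv <- resolve_intervals(track, chrom, start, end)
  out <- numeric(iv$n)
  for (chr in unique(iv$chrom)) {
    i <- which(iv$chrom == chr)
    v <- IRanges::Views(track$cov[[chr]], start = iv$start[i] + 1,
                        end = iv$end[i])
    out[i] <- statf(v)
  }
  out
}

#' Length-weighted mean signal over intervals
#'
#' @param track a [coverage_track].
#' @param chrom,start,end parallel vectors of 0-based half-open intervals;
#'   empty intervals are an error.
#' @return numeric vector of per-interval means.
#' @export
mean_signal <- function(track, chrom, start, end) {
  view_stat(track, chrom, start, end, IRanges::viewMeans)
}

#' Signal integral (value x bp) over intervals
#' @inheritParams mean_signal
#' @export
sum_signal <- function(track, chrom, start, end) {
  view_stat(track, chrom, start, end, IRanges::viewSums)
}

#' Rescale a raw track to RPM or spike-in normalized signal
#'
#' Multiplies every value by 1e6 and divides by the relevant aligned-read
#' count (one correctly rounded division per value, as in
#' [reads_to_coverage]).
#'
#' @param track a raw [coverage_track].
#' @param summary an [alignment_summary].
#' @param mode `"rpm"` or `"spikein"`.
#' @export
normalize_track <- function(track, summary, mode = c("rpm", "spikein")) {
  mode <- match.arg(mode)
  compute_factors(summary, which = mode)
  n <- if (mode == "rpm") summary$n_primary else summary$n_spikein
  cov <- lapply(track$cov, function(r) (r * 1e6) / n)
  coverage_track(cov, track$chrom_sizes, tag = mode)
}

#' Pseudocounted ratio of two tracks
#'
#' Computes `(num + eps) / (den + eps)` base by base; where both tracks are
#' zero the ratio is 1 (eps/eps). Used for histone-normalized signal, e.g.
#' H3K36me3 over total H3.
#'
#' @param num,den coverage tracks over the same chromosome universe.
#' @param eps pseudocount, must be > 0 (default 0.5).
#' @return A [coverage_track] tagged `ratio`.
#' @export
ratio_track <- function(num, den, eps = 0.5) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
  if (!identical(names(num$chrom_sizes), names(den$chrom_sizes)) ||
      !all(num$chrom_sizes == den$chrom_sizes)) {
    stop("tracks are on different chromosome universes")
  }
  cov <- lapply(names(num$chrom_sizes), function(chr) {
    (num$cov[[chr]] + eps) / (den$cov[[chr]] + eps)
  })
  names(cov) <- names(num$chrom_sizes)
  coverage_track(cov, num$chrom_sizes, tag = "ratio")
}

#' Total signal mass of a track (value x bp summed over the genome)
#' @param track a [coverage_track].
#' @export
track_total <- function(track) {
  sum(vapply(track$cov, function(r) {
    sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r))
  }, numeric(1)))
}

track_runs <- function(track) {
  do.call(rbind, lapply(names(track$cov), function(chr) {
    r <- track$cov[[chr]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - as.numeric(rl)
    keep <- rv != 0
    data.frame(chrom = chr, start = starts[keep], end = ends[keep],
               value = as.numeric(rv[keep]))
  }))
}

#' Write a track as 4-column bedGraph (0-based half-open)
#'
#' Only nonzero runs are written; values are formatted with 17 significant
#' digits so the write/read round trip is bit-exact.
#'
#' @param track a [coverage_track].
#' @param path output file path.
#' @export
write_bedgraph <- function(track, path) {
  runs <- track_runs(track)
  lines <- if (is.null(runs) || nrow(runs) == 0) character(0) else {
    sprintf("%s\t%d\t%d\t%.17g", runs$chrom, as.integer(runs$start),
            as.integer(runs$end), runs$value)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Input intervals may be unsorted (they are sorted internally); overlapping
#' intervals are an error because a track is a function of position. Bases not
#' covered by any interval get value 0.
#'
#' @param path bedGraph file path (4 columns, 0-based half-open).
#' @param chrom_sizes named vector of chromosome lengths; inferred from the
#'   maximum interval end per chromosome when `NULL`.
#' @param tag normalization tag to attach (the file does not record one).
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL, tag = "raw") {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t",
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric")),
    error = function(e) data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), value = numeric())
  )
  df <- df[order(df$chrom, df$start), ]
  if (is.null(chrom_sizes)) {
    if (nrow(df) == 0) stop("empty bedGraph and no chrom_sizes given")
    mx <- tapply(df$end, df$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(mx), names(mx))
  }
  cov <- lapply(names(chrom_sizes), function(chr) {
    d <- df[df$chrom == chr, ]
    if (nrow(d) == 0) return(S4Vectors::Rle(0, chrom_sizes[[chr]]))
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping bedGraph intervals on ", chr)
    }
    if (any(d$end > chrom_sizes[[chr]])) {
      stop("bedGraph interval beyond chromosome end on ", chr)
    }
    runs_to_rle(d$start, d$end, d$value, chrom_sizes[[chr]])
  })
  names(cov) <- names(chrom_sizes)
  coverage_track(cov, chrom_sizes, tag = tag)
}

# assemble an Rle from sorted non-overlapping runs, zero-filling the gaps;
# values are carried verbatim (no accumulation, so no floating-point drift)
runs_to_rle <- function(start, end, value, chrom_len) {
  prev <- c(0, utils::head(end, -1))
  lens <- as.vector(rbind(start - prev, end - start))
  vals <- as.vector(rbind(0, value))
  lens <- c(lens, chrom_len - end[length(end)])
  vals <- c(vals, 0)
  keep <- lens > 0
  S4Vectors::Rle(vals[keep], lens[keep])
}

#' Write a track as bigWig
#' @param track a [coverage_track].
#' @param path output .bw path.
#' @export
write_bigwig <- function(track, path) {
  runs <- track_runs(track)
  gr <- GenomicRanges::GRanges(
    runs$chrom, IRanges::IRanges(runs$start + 1, runs$end),
    score = runs$value,
    seqlengths = stats::setNames(as.integer(track$chrom_sizes),
                                 names(track$chrom_sizes))
  )
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

#' Read a bigWig file into a coverage track
#' @param path .bw path.
#' @param chrom_sizes optional named vector; taken from the file when `NULL`.
#' @param tag normalization tag to attach.
#' @export
read_bigwig <- function(path, chrom_sizes = NULL, tag = "raw") {
  gr <- rtracklayer::import.bw(path)
  if (is.null(chrom_sizes)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    chrom_sizes <- stats::setNames(as.numeric(sl), names(sl))
  }
  cov <- lapply(names(chrom_sizes), function(chr) {
    g <- gr[GenomeInfoDb::seqnames(gr) == chr]
    if (length(g) == 0) return(S4Vectors::Rle(0, chrom_sizes[[chr]]))
    g <- g[order(GenomicRanges::start(g))]
    runs_to_rle(GenomicRanges::start(g) - 1, GenomicRanges::end(g),
                g$score, chrom_sizes[[chr]])
  })
  names(cov) <- names(chrom_sizes)
  coverage_track(cov, chrom_sizes, tag = tag)
}
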