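#' Metagene bin scheme
#'
#' The scaled-gene coordinate system: `flank_bins` fixed-width bins over the
#' `flank` bp upstream of the TSS, `body_bins` near-equal bins over the gene
#' body (TSS to TES), and `flank_bins` fixed-width bins downstream of the TES.
#' Defaults give 100 bins of 20 bp per 2 kb flank plus 300 body bins — 500
#' bins per gene, with body bins of at least 2 bp for genes of at least
#' 600 bp.
#'
#' @param flank flank width in bp.
#' @param flank_bins number of bins per flank; `flank` must be a multiple.
#' @param body_bins number of gene-body bins.
#' @export
bin_scheme <- function(flank = 2000, flank_bins = 100, body_bins = 300) {
  stopifnot(flank > 0, flank_bins > 0, body_bins > 0,
            flank %% flank_bins == 0)
  structure(list(flank = flank, flank_bins = flank_bins,
                 body_bins = body_bins,
                 bin_width = flank / flank_bins,
                 total_bins = 2 * flank_bins + body_bins),
            class = "bin_scheme")
}

#' Bin one gene into the metagene coordinate system
#'
#' Produces `2 * flank_bins + body_bins` contiguous intervals in biological
#' orientation: bin 1 is always the bin furthest upstream of the TSS,
#' whichever strand the gene is on. Body bin boundaries are at
#' `round(i * L / body_bins)` from the TSS, so widths differ by at most 1 bp.
#' Bins are clipped at chromosome bounds; clipped-away bins have zero width.
#'
#' @param gene one-row data frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param scheme a [bin_scheme].
#' @param chrom_len length of the gene's chromosome in bp.
#' @return tibble with columns `bin`, `region` (`upstream` / `body` /
#'   `downstream`), `chrom`, `start`, `end`.
#' @export
bin_gene <- function(gene, scheme = bin_scheme(), chrom_len = Inf) {
  L <- gene$end - gene$start
  if (L < 2 * scheme$body_bins) {
    stop("gene span ", L, " bp is shorter than 2 bp per body bin (",
         2 * scheme$body_bins, " bp); filter genes before binning")
  }
  w <- scheme$bin_width
  fb <- scheme$flank_bins
  bb <- scheme$body_bins
  left <- gene$start - scheme$flank + w * (0:fb)
  body <- gene$start + round((0:bb) * L / bb)
  right <- gene$end + w * (0:fb)
  # 2*fb + bb + 1 boundaries: left flank (ending at the TSS), interior body
  # boundaries, right flank (starting at the TES)
  interior <- if (bb >= 2) body[2:bb] else numeric(0)
  bounds <- c(left, interior, right)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  if (identical(gene$strand, "-")) {
    starts <- rev(starts)
    ends <- rev(ends)
  }
  region <- rep(c("upstream", "body", "downstream"), c(fb, bb, fb))
  tibble::tibble(
    bin = seq_len(scheme$total_bins),
    region = region,
    chrom = gene$chrom,
    start = pmin(pmax(starts, 0), chrom_len),
    end = pmin(pmax(ends, 0), chrom_len)
  )
}

#' Average metagene profile over a gene set
#'
#' Bins every gene with [bin_gene] and averages the per-bin mean signal with
#' equal gene weighting: `values[k]` is the mean over genes of the mean track
#' signal in bin k. Genes whose full flank-extended window leaves the
#' chromosome are dropped with a warning; flank bins that merely cross a
#' chromosome edge would otherwise contribute clipped means.
#'
#' @param track a [coverage_track].
#' @param genes tibble of genes (typically from [select_metagene_genes]).
#' @param scheme a [bin_scheme].
#' @return An object of class `metagene_profile` with elements `values`
#'   (length `scheme$total_bins`), `n_genes`, `n_dropped`, `scheme`, `tag`.
#' @export
metagene_profile <- function(track, genes, scheme = bin_scheme()) {
  genes <- tibble::as_tibble(genes)
  if (nrow(genes) == 0) stop("empty gene list")
  sizes <- track$chrom_sizes[genes$chrom]
  inside <- genes$start - scheme$flank >= 0 & genes$end + scheme$flank <= sizes
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    warning(n_dropped,
            " gene(s) dropped: flank window extends past a chromosome edge")
  }
  genes <- genes[inside, ]
  if (nrow(genes) == 0) stop("no genes left after chromosome-edge filtering")

  bins <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    b <- bin_gene(genes[i, ], scheme,
                  chrom_len = track$chrom_sizes[[genes$chrom[i]]])
    b$gene_idx <- i
    b
  }))
  m <- mean_signal(track, bins$chrom, bins$start, bins$end)
  mat <- matrix(m, nrow = scheme$total_bins)   # bins x genes, column-major
  structure(
    list(values = rowMeans(mat), n_genes = nrow(genes),
         n_dropped = n_dropped, scheme = scheme, tag = track$tag),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile: ", x$scheme$total_bins, " bins over ", x$n_genes,
      " genes (track: ", x$tag, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  s <- x$scheme
  data.frame(
    bin_index = seq_len(s$total_bins),
    region = rep(c("upstream", "body", "downstream"),
                 c(s$flank_bins, s$body_bins, s$flank_bins)),
    mean_signal = x$values,
    n_genes = x$n_genes
  )
}

#' Write a metagene profile as TSV
#' @param p a [metagene_profile].
#' @param path output path.
#' @export
write_metagene_tsv <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' 5'/3' body skew of a metagene profile
#'
#' `log2` ratio of the mean signal over the 5' half of the gene-body bins to
#' the mean over the 3' half, with a pseudocount: positive values indicate a
#' 5'-heavy profile, negative a 3'-heavy one, and symmetric profiles score 0.
#'
#' @param p a [metagene_profile].
#' @param eps pseudocount shared with [ratio_track]'s default.
#' @export
body_skew <- function(p, eps = 0.5) {
  s <- p$scheme
  if (s$body_bins %% 2 != 0) stop("body_bins must be even for the skew split")
  body <- p$values[(s$flank_bins + 1):(s$flank_bins + s$body_bins)]
  half <- s$body_bins / 2
  m5 <- mean(body[seq_len(half)])
  m3 <- mean(body[half + seq_len(half)])
  log2((m5 + eps) / (m3 + eps))
}
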