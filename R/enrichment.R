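#' Per-transcript exon and intron signal totals
#'
#' For each transcript: the signal integral and total length over its exons
#' and over its introns (gaps between consecutive exons), plus the
#' length-weighted means. Exon and intron intervals are half-open and disjoint
#' by construction, so each base contributes to exactly one category.
#'
#' @param track a [coverage_track].
#' @param ann a [genome_annotation].
#' @param transcript_ids transcripts to score; default all.
#' @return tibble with columns `transcript_id`, `gene_id`, `n_exons`,
#'   `exon_total`, `exon_len`, `exon_mean`, `intron_total`, `intron_len`,
#'   `intron_mean`.
#' @export
transcript_signal <- function(track, ann, transcript_ids = NULL) {
  ex <- ann$exons
  if (!is.null(transcript_ids)) ex <- ex[ex$transcript_id %in% transcript_ids, ]
  if (nrow(ex) == 0) stop("no transcripts to score")
  ins <- derive_introns(ann, unique(ex$transcript_id))

  ex$signal <- sum_signal(track, ex$chrom, ex$start, ex$end)
  exs <- ex |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(gene_id = .data$gene_id[1], n_exons = dplyr::n(),
                     exon_total = sum(.data$signal),
                     exon_len = sum(.data$end - .data$start),
                     .groups = "drop")
  if (nrow(ins) > 0) {
    ins$signal <- sum_signal(track, ins$chrom, ins$start, ins$end)
    inl <- ins |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::summarise(intron_total = sum(.data$signal),
                       intron_len = sum(.data$end - .data$start),
                       .groups = "drop")
  } else {
    inl <- tibble::tibble(transcript_id = character(),
                          intron_total = numeric(), intron_len = numeric())
  }
  out <- dplyr::left_join(exs, inl, by = "transcript_id")
  out$intron_total[is.na(out$intron_total)] <- 0
  out$intron_len[is.na(out$intron_len)] <- 0
  out$exon_mean <- out$exon_total / out$exon_len
  out$intron_mean <- ifelse(out$intron_len > 0,
                            out$intron_total / out$intron_len, NA_real_)
  out
}

#' Pooled exon vs intron average signal
#'
#' The average exon signal is the total signal over all exons of the supplied
#' transcripts divided by the total exon length; the average intron signal is
#' defined analogously. Also reports their ratio.
#'
#' @param track a [coverage_track].
#' @param ann a [genome_annotation].
#' @param transcript_ids transcript set, typically from
#'   [select_exon_transcripts]; an empty set is an error.
#' @return list with `avg_exon`, `avg_intron`, `ratio`.
#' @export
global_exon_intron_signal <- function(track, ann, transcript_ids) {
  if (length(transcript_ids) == 0) stop("empty transcript list")
  ts <- transcript_signal(track, ann, transcript_ids)
  avg_exon <- sum(ts$exon_total) / sum(ts$exon_len)
  tot_intron_len <- sum(ts$intron_len)
  if (tot_intron_len == 0) {
    stop("total intron length is zero: exon/intron ratio undefined")
  }
  avg_intron <- sum(ts$intron_total) / tot_intron_len
  list(avg_exon = avg_exon, avg_intron = avg_intron,
       ratio = avg_exon / avg_intron)
}

#' Per-transcript exon/intron enrichment scores
#'
#' The enrichment score of a transcript is its mean exon signal divided by its
#' mean intron signal. Transcripts with a single exon (no introns) or with
#' zero intron signal have an undefined score: they are flagged, counted and
#' excluded from aggregates rather than pseudocounted.
#'
#' @param track a [coverage_track].
#' @param ann a [genome_annotation].
#' @param transcript_ids transcripts to score; default all.
#' @param eps optional pseudocount; when > 0 the score becomes
#'   `(exon_mean + eps) / (intron_mean + eps)` and is defined whenever the
#'   transcript has introns.
#' @return tibble with `transcript_id`, `gene_id`, `exon_mean`, `intron_mean`,
#'   `score`, `defined`; attributes `n_defined` and `n_excluded`.
#' @export
per_transcript_enrichment <- function(track, ann, transcript_ids = NULL,
                                      eps = 0) {
  ts <- transcript_signal(track, ann, transcript_ids)
  if (eps > 0) {
    defined <- ts$intron_len > 0
    score <- ifelse(defined, (ts$exon_mean + eps) / (ts$intron_mean + eps),
                    NA_real_)
  } else {
    defined <- ts$intron_len > 0 & !is.na(ts$intron_mean) & ts$intron_mean > 0
    score <- ifelse(defined, ts$exon_mean / ts$intron_mean, NA_real_)
  }
  out <- tibble::tibble(
    transcript_id = ts$transcript_id, gene_id = ts$gene_id,
    exon_mean = ts$exon_mean, intron_mean = ts$intron_mean,
    score = score, defined = defined
  )
  attr(out, "n_defined") <- sum(defined)
  attr(out, "n_excluded") <- sum(!defined)
  out
}

#' Summarize enrichment scores over named gene sets
#'
#' For each set (e.g. splicing-Up, splicing-Down, All) the defined scores of
#' its member genes are summarized with n, mean, median and Tukey boxplot
#' statistics. Set members absent from the score table are ignored with a
#' warning.
#'
#' @param scores tibble from [per_transcript_enrichment].
#' @param gene_sets named list of gene-id character vectors.
#' @return tibble with one row per set: `set`, `n`, `mean`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
aggregate_enrichment <- function(scores, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  rows <- lapply(names(gene_sets), function(nm) {
    ids <- gene_sets[[nm]]
    missing <- setdiff(ids, scores$gene_id)
    if (length(missing) > 0) {
      warning("set '", nm, "': ", length(missing),
              " gene id(s) absent from the score table are ignored")
    }
    x <- scores$score[scores$gene_id %in% ids & scores$defined]
    if (length(x) == 0) {
      return(tibble::tibble(set = nm, n = 0L, mean = NA_real_,
                            median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                            whisker_low = NA_real_, whisker_high = NA_real_,
                            n_outliers = 0L))
    }
    b <- boxplot_summary(x)
    tibble::tibble(set = nm, n = b$n, mean = mean(x), median = b$median,
                   q1 = b$q1, q3 = b$q3, whisker_low = b$whisker_low,
                   whisker_high = b$whisker_high,
                   n_outliers = length(b$outliers))
  })
  dplyr::bind_rows(rows)
}
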