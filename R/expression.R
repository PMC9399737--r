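# TPM cutoffs used to stratify expression, per biotype: low = (0, low_max],
# high = [high_min, Inf). Genes with tpm = 0 or in the gap belong to neither.
TPM_CUTOFFS <- list(
  protein_coding = c(low_max = 2, high_min = 4),
  lncRNA = c(low_max = 0.1, high_min = 0.5)
)

#' Stratify genes into low/high expression by TPM cutoffs
#'
#' Protein-coding genes: low is 0 < TPM <= 2, high is TPM >= 4. lncRNA genes:
#' low is 0 < TPM <= 0.1, high is TPM >= 0.5. Boundaries are inclusive;
#' silent genes (TPM = 0) and genes in the gap between the cutoffs belong to
#' neither stratum.
#'
#' @param records tibble with `gene_id`, `biotype`, `tpm`.
#' @param biotype `"protein_coding"` or `"lncRNA"`; anything else is an error.
#' @return list with character vectors `low` and `high` of gene ids.
#' @export
stratify_by_expression <- function(records, biotype) {
  if (!biotype %in% names(TPM_CUTOFFS)) {
    stop("unknown biotype '", biotype, "'; expected one of: ",
         paste(names(TPM_CUTOFFS), collapse = ", "))
  }
  cut <- TPM_CUTOFFS[[biotype]]
  r <- records[records$biotype == biotype, ]
  list(
    low = r$gene_id[r$tpm > 0 & r$tpm <= cut[["low_max"]]],
    high = r$gene_id[r$tpm >= cut[["high_min"]]]
  )
}

#' Mean signal over each gene's span
#'
#' @param track a [coverage_track].
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end`.
#' @return tibble with `gene_id` and `mean_signal`.
#' @export
gene_body_signal <- function(track, genes) {
  tibble::tibble(
    gene_id = genes$gene_id,
    mean_signal = mean_signal(track, genes$chrom, genes$start, genes$end)
  )
}

#' Tukey boxplot summary
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Whiskers extend to the most extreme data points
#' within Q1 - 1.5 IQR and Q3 + 1.5 IQR; points beyond are returned as
#' outliers.
#'
#' @param values nonempty numeric vector without NAs.
#' @param type quantile convention, passed to [stats::quantile()].
#' @return list with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
boxplot_summary <- function(values, type = 7) {
  if (length(values) == 0) stop("empty input")
  if (any(is.na(values))) stop("NA values in input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  list(
    n = length(values),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = max(min(values), lo_fence),
    whisker_high = min(max(values), hi_fence),
    outliers = sort(values[values < lo_fence | values > hi_fence])
  )
}

#' Filter differential-expression or splicing records at printed thresholds
#'
#' Differential-expression tables (with a `log2fc` column) keep rows with
#' absolute fold change >= `min_fc` (i.e. |log2fc| >= log2(min_fc)) and
#' FDR <= `fdr_max`, boundaries inclusive. Splicing event tables (with a
#' `delta_psi` column) keep rows with FDR <= `fdr_max`. A `direction` column
#' (`up` / `down`) is added from the sign of `log2fc` or `delta_psi`.
#'
#' @param records tibble with `gene_id`, `fdr` and either `log2fc` or
#'   `delta_psi`.
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_fc minimum absolute fold change for expression records
#'   (default 2).
#' @return the significant subset with a `direction` column.
#' @export
filter_significant <- function(records, fdr_max = 0.05, min_fc = 2) {
  records <- tibble::as_tibble(records)
  if (!all(c("gene_id", "fdr") %in% names(records))) {
    stop("schema error: records need 'gene_id' and 'fdr' columns")
  }
  if ("log2fc" %in% names(records)) {
    keep <- abs(records$log2fc) >= log2(min_fc) & records$fdr <= fdr_max
    out <- records[keep, ]
    out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  } else if ("delta_psi" %in% names(records)) {
    keep <- records$fdr <= fdr_max
    out <- records[keep, ]
    out$direction <- ifelse(out$delta_psi >= 0, "up", "down")
  } else {
    stop("schema error: records need a 'log2fc' or 'delta_psi' column")
  }
  out
}

#' Gene sets with increased / decreased splicing events
#'
#' `Up` contains every gene with at least one significant positive-direction
#' event, `Down` every gene with at least one negative-direction event; genes
#' with events in both directions appear in both sets.
#'
#' @param events splicing events, already passed through [filter_significant]
#'   (a `direction` column is computed from `delta_psi` if absent).
#' @return list with character vectors `Up` and `Down`.
#' @export
splice_event_gene_sets <- function(events) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) return(list(Up = character(0), Down = character(0)))
  if (!"direction" %in% names(events)) {
    events$direction <- ifelse(events$delta_psi >= 0, "up", "down")
  }
  list(
    Up = sort(unique(events$gene_id[events$direction == "up"])),
    Down = sort(unique(events$gene_id[events$direction == "down"]))
  )
}

#' Read a TPM expression table (TSV: gene_id, biotype, tpm)
#' @param path TSV path with a header row.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "biotype", "tpm")
  if (!all(need %in% names(df))) {
    stop("schema error: expression table needs columns ",
         paste(need, collapse = ", "))
  }
  tibble::as_tibble(df[, need])
}

RMATS_EVENT_TYPES <- c("SE", "A5SS", "A3SS", "MXE", "RI")

#' Read rMATS-format event tables
#'
#' Accepts one TSV per event type in the standard rMATS column layout; only
#' `GeneID`, `IncLevelDifference` and `FDR` are required (mapped to
#' `gene_id`, `delta_psi`, `fdr`). Files named after their event type (e.g.
#' `SE.MATS.JC.txt`) get that type; otherwise an `event_type` column must be
#' present.
#'
#' @param paths character vector of file paths, optionally named by event
#'   type.
#' @return tibble with `gene_id`, `event_type`, `delta_psi`, `fdr`.
#' @export
read_rmats_events <- function(paths) {
  if (is.null(names(paths))) names(paths) <- rep("", length(paths))
  rows <- lapply(seq_along(paths), function(i) {
    df <- utils::read.table(paths[i], sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
    cols <- names(df)
    gene <- if ("GeneID" %in% cols) df$GeneID else df$gene_id
    dpsi <- if ("IncLevelDifference" %in% cols) df$IncLevelDifference else
      df$delta_psi
    fdr <- if ("FDR" %in% cols) df$FDR else df$fdr
    if (is.null(gene) || is.null(dpsi) || is.null(fdr)) {
      stop("schema error in ", paths[i],
           ": need GeneID/IncLevelDifference/FDR (or gene_id/delta_psi/fdr)")
    }
    type <- names(paths)[i]
    if (!nzchar(type)) {
      hit <- RMATS_EVENT_TYPES[vapply(RMATS_EVENT_TYPES, function(t)
        grepl(paste0("(^|[^A-Z])", t, "([^A-Z]|$)"), basename(paths[i])),
        logical(1))]
      type <- if (length(hit) == 1) hit else NA_character_
    }
    if (is.na(type) && "event_type" %in% cols) type <- NULL
    tibble::tibble(
      gene_id = gene,
      event_type = if (is.null(type)) df$event_type else type,
      delta_psi = dpsi, fdr = fdr
    )
  })
  dplyr::bind_rows(rows)
}
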