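#' Gene-model container
#'
#' A `genome_annotation` bundles gene models parsed from a GTF: gene spans,
#' transcripts, exons and (when annotated) UTR intervals, together with
#' chromosome lengths. All coordinates are stored 0-based half-open (BED
#' convention); GTF input/output converts at the boundary, so interval
#' arithmetic inside the package never mixes conventions.
#'
#' @param chrom_sizes named numeric vector, chromosome -> length in bp.
#' @param genes tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @param transcripts tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param exons tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`; exons of one transcript must be non-overlapping
#'   and share chrom/strand.
#' @param utrs tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `type` (`five_prime_utr` / `three_prime_utr`); may be empty.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes, genes, transcripts, exons,
                              utrs = empty_utrs()) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  genes <- tibble::as_tibble(genes)
  transcripts <- tibble::as_tibble(transcripts)
  exons <- tibble::as_tibble(exons)
  utrs <- tibble::as_tibble(utrs)

  check_intervals(genes, chrom_sizes, "gene")
  check_intervals(transcripts, chrom_sizes, "transcript")
  check_intervals(exons, chrom_sizes, "exon")
  if (nrow(utrs) > 0) check_intervals(utrs, chrom_sizes, "UTR")

  # deterministic ordering
  genes <- dplyr::arrange(genes, .data$chrom, .data$start, .data$gene_id)
  transcripts <- dplyr::arrange(transcripts, .data$chrom, .data$start,
                                .data$transcript_id)
  exons <- dplyr::arrange(exons, .data$chrom, .data$transcript_id, .data$start)

  # exons of a transcript must not overlap
  bad <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      ok = dplyr::n() < 2 ||
        all(.data$start[-1] >= .data$end[-dplyr::n()]),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("overlapping exons within transcript(s): ",
         paste(utils::head(bad$transcript_id, 3), collapse = ", "))
  }

  structure(
    list(chrom_sizes = chrom_sizes, genes = genes, transcripts = transcripts,
         exons = exons, utrs = utrs),
    class = "genome_annotation"
  )
}

empty_genes <- function() {
  tibble::tibble(gene_id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), biotype = character())
}

empty_transcripts <- function() {
  tibble::tibble(transcript_id = character(), gene_id = character(),
                 chrom = character(), start = numeric(), end = numeric(),
                 strand = character())
}

empty_exons <- function() {
  tibble::tibble(transcript_id = character(), gene_id = character(),
                 chrom = character(), start = numeric(), end = numeric(),
                 strand = character())
}

empty_utrs <- function() {
  tibble::tibble(transcript_id = character(), chrom = character(),
                 start = numeric(), end = numeric(), strand = character(),
                 type = character())
}

check_intervals <- function(df, chrom_sizes, what) {
  if (nrow(df) == 0) return(invisible(TRUE))
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("invalid ", what, " interval: need 0 <= start < end")
  }
  if (!all(df$chrom %in% names(chrom_sizes))) {
    stop(what, " on unknown chromosome: ",
         paste(setdiff(unique(df$chrom), names(chrom_sizes)), collapse = ", "))
  }
  if (any(df$end > chrom_sizes[df$chrom])) {
    stop(what, " interval exceeds chromosome length")
  }
  if (!all(df$strand %in% c("+", "-", "*"))) {
    stop(what, " strand must be one of '+', '-', '*'")
  }
  invisible(TRUE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '[ =]+"?([^";]+)"?'), attrs))
  vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_,
         character(1))
}

#' Read an Ensembl-dialect GTF into a genome_annotation
#'
#' Parses `gene`, `transcript`, `exon`, `five_prime_utr` and `three_prime_utr`
#' features. GTF coordinates (1-based, closed) are converted to the internal
#' 0-based half-open convention. Gene or transcript rows missing from the file
#' are reconstructed from their exons. Malformed lines raise an error naming
#' the line number.
#'
#' @param path GTF file path.
#' @param chrom_sizes optional named vector of chromosome lengths; when `NULL`
#'   each length is inferred as the maximum annotated end plus 10 kb of
#'   intergenic slack.
#' @return A [genome_annotation].
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    cs <- if (is.null(chrom_sizes)) c(chr1 = 1) else chrom_sizes
    return(genome_annotation(cs, empty_genes(), empty_transcripts(),
                             empty_exons()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9)) {
    stop("malformed GTF line ", lineno[which(nf != 9)[1]],
         ": expected 9 tab-separated fields, found ", nf[which(nf != 9)[1]])
  }
  m <- do.call(rbind, parts)
  feat <- m[, 3]
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  badc <- which(is.na(start1) | is.na(end1) | end1 < start1)
  if (length(badc) > 0) {
    stop("malformed GTF line ", lineno[badc[1]], ": bad coordinates")
  }
  df <- tibble::tibble(
    chrom = m[, 1], feature = feat,
    start = start1 - 1, end = end1,           # 0-based half-open
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
    attrs = m[, 9], line = lineno
  )

  used <- c("gene", "transcript", "exon", "five_prime_utr", "three_prime_utr")
  df <- df[df$feature %in% used, , drop = FALSE]

  df$gene_id <- gtf_attr(df$attrs, "gene_id")
  df$transcript_id <- gtf_attr(df$attrs, "transcript_id")
  df$biotype <- gtf_attr(df$attrs, "gene_biotype")

  ex <- df[df$feature == "exon", ]
  if (any(is.na(ex$transcript_id))) {
    stop("malformed GTF line ", ex$line[which(is.na(ex$transcript_id))[1]],
         ": exon without transcript_id")
  }
  if (any(is.na(df$gene_id))) {
    stop("malformed GTF line ", df$line[which(is.na(df$gene_id))[1]],
         ": missing gene_id")
  }

  exons <- tibble::tibble(
    transcript_id = ex$transcript_id, gene_id = ex$gene_id,
    chrom = ex$chrom, start = ex$start, end = ex$end, strand = ex$strand
  )

  # transcripts: explicit rows, completed from exon spans
  tx_rows <- df[df$feature == "transcript", ]
  tx_from_ex <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(gene_id = .data$gene_id[1], chrom = .data$chrom[1],
                     start = min(.data$start), end = max(.data$end),
                     strand = .data$strand[1], .groups = "drop")
  transcripts <- tibble::tibble(
    transcript_id = tx_rows$transcript_id, gene_id = tx_rows$gene_id,
    chrom = tx_rows$chrom, start = tx_rows$start, end = tx_rows$end,
    strand = tx_rows$strand
  )
  missing_tx <- setdiff(tx_from_ex$transcript_id, transcripts$transcript_id)
  transcripts <- dplyr::bind_rows(
    transcripts, tx_from_ex[tx_from_ex$transcript_id %in% missing_tx, ]
  )

  g_rows <- df[df$feature == "gene", ]
  genes <- tibble::tibble(
    gene_id = g_rows$gene_id, chrom = g_rows$chrom, start = g_rows$start,
    end = g_rows$end, strand = g_rows$strand,
    biotype = ifelse(is.na(g_rows$biotype), "other", g_rows$biotype)
  )
  g_from_tx <- transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), strand = .data$strand[1],
                     .groups = "drop")
  missing_g <- setdiff(g_from_tx$gene_id, genes$gene_id)
  if (length(missing_g) > 0) {
    bt <- df$biotype[match(missing_g, df$gene_id)]
    add <- g_from_tx[g_from_tx$gene_id %in% missing_g, ]
    add$biotype <- ifelse(is.na(bt[match(add$gene_id, missing_g)]), "other",
                          bt[match(add$gene_id, missing_g)])
    genes <- dplyr::bind_rows(genes, add)
  }

  u_rows <- df[df$feature %in% c("five_prime_utr", "three_prime_utr"), ]
  utrs <- tibble::tibble(
    transcript_id = u_rows$transcript_id, chrom = u_rows$chrom,
    start = u_rows$start, end = u_rows$end, strand = u_rows$strand,
    type = u_rows$feature
  )

  if (is.null(chrom_sizes)) {
    mx <- tapply(df$end, df$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(mx) + 10000, names(mx))
  }
  genome_annotation(chrom_sizes, genes, transcripts, exons, utrs)
}

#' Write a genome_annotation as GTF
#'
#' Emits gene, transcript, exon and UTR features with Ensembl-style
#' attributes, converting back to 1-based closed coordinates. Output is
#' deterministic for a given annotation (fixed field formatting and ordering),
#' so identical annotations yield byte-identical files.
#'
#' @param ann a [genome_annotation].
#' @param path output file path.
#' @export
write_gtf <- function(ann, path) {
  fmt <- function(chrom, feature, start, end, strand, attrs) {
    sprintf("%s\tchromprofiler\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feature, as.integer(start + 1), as.integer(end), strand,
            attrs)
  }
  g <- ann$genes
  gl <- fmt(g$chrom, "gene", g$start, g$end, g$strand,
            sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype))
  tx <- dplyr::left_join(ann$transcripts,
                         g[, c("gene_id", "biotype")], by = "gene_id")
  tl <- fmt(tx$chrom, "transcript", tx$start, tx$end, tx$strand,
            sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                    tx$gene_id, tx$transcript_id, tx$biotype))
  ex <- ann$exons
  el <- fmt(ex$chrom, "exon", ex$start, ex$end, ex$strand,
            sprintf('gene_id "%s"; transcript_id "%s";',
                    ex$gene_id, ex$transcript_id))
  ul <- character(0)
  if (nrow(ann$utrs) > 0) {
    u <- ann$utrs
    ul <- fmt(u$chrom, u$type, u$start, u$end, u$strand,
              sprintf('transcript_id "%s";', u$transcript_id))
  }
  writeLines(c(gl, tl, el, ul), path)
  invisible(path)
}

#' Derive introns from transcript exon structures
#'
#' Introns are the gaps between consecutive exons of a transcript; abutting
#' exons produce no (zero-length) intron, and single-exon transcripts have
#' none. Exons and introns of a transcript tile its span exactly.
#'
#' @param ann a [genome_annotation].
#' @param transcript_ids optional character vector restricting the transcripts.
#' @return tibble with columns `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
derive_introns <- function(ann, transcript_ids = NULL) {
  ex <- ann$exons
  if (!is.null(transcript_ids)) {
    ex <- ex[ex$transcript_id %in% transcript_ids, ]
  }
  if (nrow(ex) == 0) {
    return(tibble::tibble(transcript_id = character(), gene_id = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), strand = character()))
  }
  ex |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::reframe(
      gene_id = .data$gene_id[1], chrom = .data$chrom[1],
      intron_start = utils::head(.data$end, -1),
      intron_end = utils::tail(.data$start, -1),
      strand = .data$strand[1]
    ) |>
    dplyr::rename(start = "intron_start", end = "intron_end") |>
    dplyr::filter(.data$end > .data$start) |>
    dplyr::arrange(.data$chrom, .data$start, .data$transcript_id)
}

#' Select isolated protein-coding genes for metagene profiling
#'
#' Keeps protein-coding genes whose annotated span is at least `min_len` bp
#' long and whose flank-extended window (2 kb upstream of the TSS to 2 kb
#' downstream of the TES by default, clipped at chromosome bounds) intersects
#' no other gene's span — of any biotype, on either strand.
#'
#' @param ann a [genome_annotation].
#' @param min_len minimum gene span length in bp (default 600).
#' @param flank window extension on each side in bp (default 2000).
#' @return tibble of the selected genes (same columns as `ann$genes`).
#' @export
select_metagene_genes <- function(ann, min_len = 600, flank = 2000) {
  stopifnot(flank >= 0)
  g <- ann$genes
  if (nrow(g) == 0) return(g)
  cand <- g[g$biotype == "protein_coding" & (g$end - g$start) >= min_len, ]
  if (nrow(cand) == 0) return(cand)
  win_start <- pmax(0, cand$start - flank)
  win_end <- pmin(ann$chrom_sizes[cand$chrom], cand$end + flank)
  win <- GenomicRanges::GRanges(cand$chrom,
                                IRanges::IRanges(win_start + 1, win_end))
  spans <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1, g$end))
  hits <- GenomicRanges::findOverlaps(win, spans, ignore.strand = TRUE)
  other <- cand$gene_id[S4Vectors::queryHits(hits)] !=
    g$gene_id[S4Vectors::subjectHits(hits)]
  lonely <- !(seq_len(nrow(cand)) %in% S4Vectors::queryHits(hits)[other])
  dplyr::arrange(cand[lonely, ], .data$chrom, .data$start, .data$gene_id)
}

#' Select one non-overlapping transcript per protein-coding gene
#'
#' For each protein-coding gene the transcript with the longest annotated span
#' is chosen (ties broken by lexicographically smallest id); every chosen
#' transcript whose span overlaps any other chosen transcript's span is then
#' removed, ignoring strand — both members of an overlapping pair are dropped,
#' so the result has zero pairwise overlaps by construction.
#'
#' @param ann a [genome_annotation].
#' @return tibble of the retained transcripts, sorted by (chrom, start).
#' @export
select_exon_transcripts <- function(ann) {
  tx <- dplyr::left_join(ann$transcripts,
                         ann$genes[, c("gene_id", "biotype")], by = "gene_id")
  tx <- tx[tx$biotype == "protein_coding", ]
  if (nrow(tx) == 0) return(empty_transcripts())
  longest <- tx |>
    dplyr::mutate(len = .data$end - .data$start) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$len),
                   .data$transcript_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  gr <- GenomicRanges::GRanges(longest$chrom,
                               IRanges::IRanges(longest$start + 1,
                                                longest$end))
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  drop <- unique(S4Vectors::queryHits(hits))
  keep <- longest[setdiff(seq_len(nrow(longest)), drop), ]
  keep$len <- NULL
  keep$biotype <- NULL
  dplyr::arrange(keep, .data$chrom, .data$start)
}

#' Write an interval table as BED6
#'
#' @param df tibble with `chrom`, `start`, `end`, `strand` and an id column.
#' @param path output path.
#' @param name_col column used for the BED name field.
#' @export
write_bed6 <- function(df, path, name_col = "gene_id") {
  out <- data.frame(df$chrom, as.integer(df$start), as.integer(df$end),
                    df[[name_col]], 0L, df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
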