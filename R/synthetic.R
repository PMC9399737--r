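#' Synthetic genome specification
#'
#' Parameters for the synthetic annotation generator. Defaults describe a
#' compact genome whose structure exercises every selection filter: two 3.5 Mb
#' chromosomes carrying 300 genes of 2–9 exons (150–900 bp) separated by
#' introns of 400–3000 bp, intergenic gaps of 500–8000 bp (so some neighbors
#' genuinely violate the ±2 kb isolation filter), 10% lncRNA biotype, and two
#' nested antisense gene pairs whose transcripts overlap ignoring strand.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param n_genes number of sequentially placed genes.
#' @param exon_count_range integer range of exons per transcript.
#' @param exon_len_range,intron_len_range,intergene_gap_range bp ranges.
#' @param lnc_fraction fraction of genes labeled lncRNA.
#' @param n_overlap_pairs nested antisense gene pairs to plant.
#' @param extra_transcript_prob probability a gene gets a second, shorter
#'   transcript (a prefix of its exons).
#' @param seed RNG seed; all outputs are reproducible from it.
#' @export
synth_genome_spec <- function(n_chroms = 2, chrom_len = 3.5e6, n_genes = 300,
                              exon_count_range = c(2, 9),
                              exon_len_range = c(150, 900),
                              intron_len_range = c(400, 3000),
                              intergene_gap_range = c(500, 8000),
                              lnc_fraction = 0.1, n_overlap_pairs = 2,
                              extra_transcript_prob = 0.3, seed = 1) {
  stopifnot(n_chroms >= 1, chrom_len > 0, n_genes >= 0,
            all(exon_count_range >= 1), all(exon_len_range > 0),
            all(intron_len_range > 0), all(intergene_gap_range > 0),
            lnc_fraction >= 0, lnc_fraction <= 1, n_overlap_pairs >= 0,
            extra_transcript_prob >= 0, extra_transcript_prob <= 1)
  structure(
    list(n_chroms = n_chroms, chrom_len = chrom_len, n_genes = n_genes,
         exon_count_range = exon_count_range,
         exon_len_range = exon_len_range,
         intron_len_range = intron_len_range,
         intergene_gap_range = intergene_gap_range,
         lnc_fraction = lnc_fraction, n_overlap_pairs = n_overlap_pairs,
         extra_transcript_prob = extra_transcript_prob, seed = seed),
    class = "synth_genome_spec"
  )
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic annotation with ground truth
#'
#' Genes are placed sequentially along each chromosome with random intergenic
#' gaps and alternating strands; each gene has one full-length transcript and,
#' with some probability, a shorter second transcript. Nested antisense genes
#' are planted inside large hosts so that strand-ignored transcript overlap
#' removal has true positives. The ground-truth record computes, by
#' brute-force all-pairs loops independent of the package's interval
#' machinery, which genes pass the metagene isolation filter and which
#' transcripts survive longest-transcript selection plus overlap removal.
#'
#' @param spec a [synth_genome_spec].
#' @return list with elements `annotation` (a [genome_annotation]) and
#'   `truth` (gene and transcript tibbles plus the spec).
#' @export
generate_annotation <- function(spec = synth_genome_spec()) {
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  chrom_sizes <- stats::setNames(rep(spec$chrom_len, spec$n_chroms), chroms)

  genes <- list(); transcripts <- list(); exons <- list()
  gi <- 0
  add_gene <- function(gene_id, chrom, start, strand, biotype,
                       exon_lens, intron_lens, extra = FALSE) {
    k <- length(exon_lens)
    widths <- numeric(2 * k - 1)
    widths[seq(1, 2 * k - 1, by = 2)] <- exon_lens
    if (k > 1) widths[seq(2, 2 * k - 2, by = 2)] <- intron_lens
    bounds <- start + c(0, cumsum(widths))
    ex_start <- bounds[seq(1, 2 * k - 1, by = 2)]
    ex_end <- bounds[seq(2, 2 * k, by = 2)]
    end <- bounds[length(bounds)]
    tx1 <- paste0("TX", gene_id, ".1")
    g <- tibble::tibble(gene_id = gene_id, chrom = chrom, start = start,
                        end = end, strand = strand, biotype = biotype)
    tx <- tibble::tibble(transcript_id = tx1, gene_id = gene_id,
                         chrom = chrom, start = start, end = end,
                         strand = strand)
    e <- tibble::tibble(transcript_id = tx1, gene_id = gene_id, chrom = chrom,
                        start = ex_start, end = ex_end, strand = strand)
    if (extra && k >= 2) {
      m <- sample(seq_len(k - 1), 1)
      tx2 <- paste0("TX", gene_id, ".2")
      tx <- dplyr::bind_rows(tx, tibble::tibble(
        transcript_id = tx2, gene_id = gene_id, chrom = chrom,
        start = start, end = ex_end[m], strand = strand))
      e <- dplyr::bind_rows(e, tibble::tibble(
        transcript_id = tx2, gene_id = gene_id, chrom = chrom,
        start = ex_start[seq_len(m)], end = ex_end[seq_len(m)],
        strand = strand))
    }
    list(gene = g, tx = tx, exons = e, end = end)
  }

  n_lnc <- round(spec$lnc_fraction * spec$n_genes)
  lnc_idx <- if (n_lnc > 0) sample(seq_len(spec$n_genes), n_lnc) else integer(0)

  chrom_i <- 1
  cursor <- 0
  placed <- 0
  while (placed < spec$n_genes) {
    gap <- rint(1, spec$intergene_gap_range)
    k <- rint(1, spec$exon_count_range)
    ex_lens <- rint(k, spec$exon_len_range)
    in_lens <- if (k > 1) rint(k - 1, spec$intron_len_range) else numeric(0)
    L <- sum(ex_lens) + sum(in_lens)
    start <- cursor + gap
    if (start + L > spec$chrom_len) {
      chrom_i <- chrom_i + 1
      if (chrom_i > spec$n_chroms) {
        stop("genes do not fit: increase chrom_len or n_chroms")
      }
      cursor <- 0
      next
    }
    placed <- placed + 1
    gi <- gi + 1
    id <- sprintf("GSYN%04d", gi)
    res <- add_gene(
      id, chroms[chrom_i], start,
      strand = if (placed %% 2 == 1) "+" else "-",
      biotype = if (placed %in% lnc_idx) "lncRNA" else "protein_coding",
      ex_lens, in_lens,
      extra = stats::runif(1) < spec$extra_transcript_prob
    )
    genes[[length(genes) + 1]] <- res$gene
    transcripts[[length(transcripts) + 1]] <- res$tx
    exons[[length(exons) + 1]] <- res$exons
    cursor <- res$end
  }

  genes <- dplyr::bind_rows(genes)
  # plant nested antisense genes inside large multi-exon hosts
  if (spec$n_overlap_pairs > 0 && nrow(genes) > 0) {
    hosts <- genes[genes$end - genes$start >= 4000 &
                     genes$biotype == "protein_coding", ]
    n_pairs <- min(spec$n_overlap_pairs, nrow(hosts))
    if (n_pairs > 0) {
      pick <- hosts[sample(nrow(hosts), n_pairs), ]
      for (j in seq_len(n_pairs)) {
        gi <- gi + 1
        id <- sprintf("GSYN%04d", gi)
        host <- pick[j, ]
        e1 <- rint(1, spec$exon_len_range)
        e2 <- rint(1, spec$exon_len_range)
        i1 <- min(rint(1, spec$intron_len_range),
                  host$end - host$start - e1 - e2 - 1000)
        i1 <- max(i1, 50)
        res <- add_gene(id, host$chrom, host$start + 500,
                        strand = if (host$strand == "+") "-" else "+",
                        biotype = "protein_coding",
                        exon_lens = c(e1, e2), intron_lens = i1)
        genes <- dplyr::bind_rows(genes, res$gene)
        transcripts[[length(transcripts) + 1]] <- res$tx
        exons[[length(exons) + 1]] <- res$exons
      }
    }
  }
  transcripts <- dplyr::bind_rows(transcripts)
  exons <- dplyr::bind_rows(exons)
  if (nrow(genes) == 0) {
    genes <- empty_genes(); transcripts <- empty_transcripts()
    exons <- empty_exons()
  }

  ann <- genome_annotation(chrom_sizes, genes, transcripts, exons)

  # ---- brute-force ground truth (independent all-pairs loops) ----
  g <- ann$genes
  isolated <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    ws <- max(0, g$start[i] - 2000)
    we <- min(chrom_sizes[[g$chrom[i]]], g$end[i] + 2000)
    hit <- FALSE
    for (j in seq_len(nrow(g))) {
      if (i == j || g$chrom[j] != g$chrom[i]) next
      if (ws < g$end[j] && g$start[j] < we) { hit <- TRUE; break }
    }
    isolated[i] <- !hit
  }
  truth_genes <- tibble::tibble(
    gene_id = g$gene_id, span_len = g$end - g$start, isolated = isolated,
    metagene_eligible = g$biotype == "protein_coding" &
      (g$end - g$start) >= 600 & isolated
  )

  tx <- ann$transcripts
  bt <- g$biotype[match(tx$gene_id, g$gene_id)]
  longest <- logical(nrow(tx))
  for (gid in unique(tx$gene_id)) {
    i <- which(tx$gene_id == gid)
    len <- tx$end[i] - tx$start[i]
    best <- i[order(-len, tx$transcript_id[i])][1]
    longest[best] <- TRUE
  }
  chosen <- which(longest & bt == "protein_coding")
  removed <- logical(nrow(tx))
  for (a in chosen) {
    for (b in chosen) {
      if (a == b || tx$chrom[a] != tx$chrom[b]) next
      if (tx$start[a] < tx$end[b] && tx$start[b] < tx$end[a]) {
        removed[a] <- TRUE
        break
      }
    }
  }
  truth_tx <- tibble::tibble(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    longest = longest, coding = bt == "protein_coding",
    overlap_removed = removed,
    selected = longest & bt == "protein_coding" & !removed
  )

  list(annotation = ann,
       truth = list(genes = truth_genes, transcripts = truth_tx, spec = spec))
}

#' Signal specification for synthetic coverage
#'
#' Ground-truth parameters of the expected per-base coverage inside genes:
#' `lambda(x) = base_depth * tpm^expr_coupling * (rho on exons, 1 on introns)
#' * (1 + gamma * (pos(x)/L - 0.5))`, where pos runs 5' to 3' along the gene.
#' `gamma > 0` raises coverage toward the 3' end (the canonical skew of
#' co-transcriptionally deposited marks); intergenic background is
#' `background_frac * base_depth`.
#'
#' @param rho exon:intron signal ratio (> 0).
#' @param gamma linear positional gradient in `[-1, 1]`.
#' @param base_depth mean intron coverage at TPM coupling 1.
#' @param expr_coupling exponent linking TPM to signal amplitude (0 = none).
#' @param spike_fraction fraction of all reads assigned to the spike-in
#'   genome, in (0, 1).
#' @param background_frac intergenic background as a fraction of `base_depth`.
#' @param noise `"none"` (track equals lambda exactly) or `"poisson"`
#'   (per-base Poisson counts with mean lambda).
#' @param seed RNG seed for the noise draws.
#' @export
signal_spec <- function(rho = 3, gamma = 0, base_depth = 30,
                        expr_coupling = 0, spike_fraction = 0.1,
                        background_frac = 0.05,
                        noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (gamma < -1 || gamma > 1) {
    stop("gamma outside [-1, 1] would give negative intensities")
  }
  stopifnot(base_depth >= 0, spike_fraction > 0, spike_fraction < 1,
            background_frac >= 0)
  structure(
    list(rho = rho, gamma = gamma, base_depth = base_depth,
         expr_coupling = expr_coupling, spike_fraction = spike_fraction,
         background_frac = background_frac, noise = noise, seed = seed),
    class = "signal_spec"
  )
}

longest_tx_ids <- function(ann) {
  tx <- ann$transcripts
  tx |>
    dplyr::mutate(len = .data$end - .data$start) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$len),
                   .data$transcript_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Generate synthetic coverage with known ground truth
#'
#' Builds the expected coverage `lambda` from the annotation's longest
#' transcript per gene and the [signal_spec], then returns either `lambda`
#' itself (`noise = "none"`) or an unbiased per-base Poisson realization of it
#' (`noise = "poisson"`) as a raw [coverage_track]. The alignment summary
#' derives the primary read count as total coverage divided by `ext`, and the
#' spike-in count from `spike_fraction`. With `emit_reads = TRUE`, 5'-anchored
#' reads are additionally sampled (fragment starts at per-base rate
#' `lambda/ext`, random strand) for exercising the read-pileup path; their
#' extended coverage is lambda convolved with the fragment kernel, so
#' boundary-sharp recovery targets use the track, not the reads.
#'
#' @param ann a [genome_annotation].
#' @param sig a [signal_spec].
#' @param expression optional expression tibble (`gene_id`, `tpm`) used when
#'   `expr_coupling != 0`.
#' @param emit_reads also sample read records (can be large; default FALSE).
#' @param ext fragment length assumed for read-count bookkeeping (bp).
#' @return list with `track` (raw [coverage_track]), `summary`
#'   (an [alignment_summary]), `reads` (tibble or NULL) and `sig`.
#' @export
generate_coverage <- function(ann, sig = signal_spec(), expression = NULL,
                              emit_reads = FALSE, ext = 150) {
  set.seed(sig$seed)
  longest <- longest_tx_ids(ann)
  bg <- sig$background_frac * sig$base_depth

  lambdas <- lapply(names(ann$chrom_sizes), function(chr) {
    n <- ann$chrom_sizes[[chr]]
    lam <- numeric(n)
    in_gene <- logical(n)
    gsel <- ann$genes[ann$genes$chrom == chr, ]
    for (i in seq_len(nrow(gsel))) {
      gene <- gsel[i, ]
      txid <- longest$transcript_id[longest$gene_id == gene$gene_id]
      ex <- ann$exons[ann$exons$transcript_id == txid, ]
      L <- gene$end - gene$start
      amp <- 1
      if (sig$expr_coupling != 0) {
        if (is.null(expression)) {
          stop("expr_coupling != 0 requires an expression table")
        }
        tpm <- expression$tpm[match(gene$gene_id, expression$gene_id)]
        amp <- if (is.na(tpm)) 0 else tpm^sig$expr_coupling
      }
      rel <- if (gene$strand == "-") (L - 1):0 else 0:(L - 1)
      ramp <- 1 + sig$gamma * ((rel + 0.5) / L - 0.5)
      mult <- rep(1, L)
      for (j in seq_len(nrow(ex))) {
        mult[(ex$start[j] - gene$start + 1):(ex$end[j] - gene$start)] <-
          sig$rho
      }
      idx <- (gene$start + 1):gene$end
      lam[idx] <- lam[idx] + sig$base_depth * amp * mult * ramp
      in_gene[idx] <- TRUE
    }
    lam[!in_gene] <- bg
    lam
  })
  names(lambdas) <- names(ann$chrom_sizes)

  values <- lapply(lambdas, function(lam) {
    if (sig$noise == "poisson") stats::rpois(length(lam), lam) else lam
  })
  cov <- lapply(values, S4Vectors::Rle)
  track <- coverage_track(cov, ann$chrom_sizes, tag = "raw")

  total <- sum(vapply(values, sum, numeric(1)))
  n_primary <- max(1, round(total / ext))
  n_spikein <- max(1, round(sig$spike_fraction / (1 - sig$spike_fraction) *
                              n_primary))
  summary <- alignment_summary(n_primary, n_spikein)

  reads <- NULL
  if (emit_reads) {
    reads <- dplyr::bind_rows(lapply(names(lambdas), function(chr) {
      lam <- lambdas[[chr]]
      k <- stats::rpois(length(lam), lam / ext)
      frag_start <- rep(which(k > 0) - 1, k[k > 0])
      if (length(frag_start) == 0) {
        return(tibble::tibble(chrom = character(), pos = numeric(),
                              strand = character()))
      }
      minus <- stats::runif(length(frag_start)) < 0.5
      anchor <- ifelse(minus, frag_start + ext, frag_start)
      strand <- ifelse(minus, "-", "+")
      # a minus anchor at the chromosome end is not addressable; flip it
      flip <- anchor >= length(lam)
      anchor[flip] <- frag_start[flip]
      strand[flip] <- "+"
      tibble::tibble(chrom = chr, pos = anchor, strand = strand)
    }))
  }
  list(track = track, summary = summary, reads = reads, sig = sig,
       lambda = lambdas)
}

#' Generate a synthetic TPM expression table
#'
#' TPMs are drawn log-normally with a small zero-inflated fraction; after the
#' draw, one gene per biotype stratum is pinned into the stratum if the draw
#' left it empty, so low/high sets are guaranteed nonempty under the printed
#' cutoffs. Ground truth records each gene's stratum.
#'
#' @param ann a [genome_annotation].
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal parameters of the TPM draw.
#' @param zero_fraction fraction of silent (TPM = 0) genes.
#' @return list with `expression` (tibble `gene_id`, `biotype`, `tpm`) and
#'   `truth` (tibble `gene_id`, `stratum`).
#' @export
generate_expression <- function(ann, seed = 1, meanlog = 1, sdlog = 1.5,
                                zero_fraction = 0.05) {
  set.seed(seed)
  g <- ann$genes
  n <- nrow(g)
  tpm <- stats::rlnorm(n, meanlog, sdlog)
  nz <- round(zero_fraction * n)
  if (nz > 0) tpm[sample(n, nz)] <- 0

  for (bt in intersect(unique(g$biotype), names(TPM_CUTOFFS))) {
    cut <- TPM_CUTOFFS[[bt]]
    i <- which(g$biotype == bt)
    if (length(i) == 0) next
    if (!any(tpm[i] > 0 & tpm[i] <= cut[["low_max"]])) {
      tpm[i[1]] <- cut[["low_max"]] / 2
    }
    if (!any(tpm[i] >= cut[["high_min"]]) && length(i) >= 2) {
      tpm[i[2]] <- cut[["high_min"]] * 2
    }
  }
  stratum <- rep("none", n)
  for (bt in names(TPM_CUTOFFS)) {
    cut <- TPM_CUTOFFS[[bt]]
    i <- g$biotype == bt
    stratum[i & tpm > 0 & tpm <= cut[["low_max"]]] <- "low"
    stratum[i & tpm >= cut[["high_min"]]] <- "high"
  }
  list(
    expression = tibble::tibble(gene_id = g$gene_id, biotype = g$biotype,
                                tpm = tpm),
    truth = tibble::tibble(gene_id = g$gene_id, stratum = stratum)
  )
}

#' Generate rMATS-like differential splicing events with ground truth
#'
#' `n_up` genes receive one significant positive-delta-psi event and `n_down`
#' one significant negative event (FDR drawn below 0.05); `n_null` further
#' genes receive a nonsignificant event (FDR >= 0.1). Event types cycle
#' through SE, A5SS, A3SS, MXE, RI.
#'
#' @param ann a [genome_annotation].
#' @param n_up,n_down,n_null event counts.
#' @param seed RNG seed.
#' @return list with `events` (tibble `gene_id`, `event_type`, `delta_psi`,
#'   `fdr`) and `truth` (list `up`, `down` of sorted gene ids).
#' @export
generate_events <- function(ann, n_up = 15, n_down = 15, n_null = 30,
                            seed = 1) {
  set.seed(seed)
  pool <- ann$genes$gene_id[ann$genes$biotype == "protein_coding"]
  need <- n_up + n_down + n_null
  if (length(pool) < need) {
    stop("not enough protein-coding genes (", length(pool), ") for ", need,
         " events")
  }
  ids <- sample(pool, need)
  up <- ids[seq_len(n_up)]
  down <- ids[n_up + seq_len(n_down)]
  null <- ids[n_up + n_down + seq_len(n_null)]
  events <- tibble::tibble(
    gene_id = c(up, down, null),
    event_type = rep_len(RMATS_EVENT_TYPES, need),
    delta_psi = c(stats::runif(n_up, 0.1, 0.6),
                  -stats::runif(n_down, 0.1, 0.6),
                  stats::runif(n_null, -0.05, 0.05)),
    fdr = c(stats::runif(n_up + n_down, 0, 0.049),
            stats::runif(n_null, 0.1, 1))
  )
  list(events = events, truth = list(up = sort(up), down = sort(down)))
}

#' Write events as per-type rMATS-format tables
#' @param events tibble from [generate_events].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, by event type.
#' @export
write_rmats_tables <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  types <- intersect(RMATS_EVENT_TYPES, unique(events$event_type))
  paths <- stats::setNames(file.path(dir, paste0(types, ".MATS.JC.txt")),
                           types)
  for (t in types) {
    e <- events[events$event_type == t, ]
    out <- data.frame(ID = seq_len(nrow(e)), GeneID = e$gene_id,
                      geneSymbol = e$gene_id, IncLevelDifference = e$delta_psi,
                      PValue = e$fdr, FDR = e$fdr)
    utils::write.table(out, paths[[t]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}
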