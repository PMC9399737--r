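default_params <- function() {
  list(ext = 150, flank = 2000, flank_bins = 100, body_bins = 300,
       eps = 0.5, fdr_max = 0.05, min_fc = 2, mode = "spikein")
}

#' Load and validate a pipeline configuration
#'
#' A configuration is a YAML file (or an equivalent list) naming the inputs —
#' either a `synthetic` block describing a generated study, or file paths
#' (`gtf`, per-condition `tracks` as bedGraph, optional `peaks`, `expression`,
#' `events`) — plus analysis parameters. Missing referenced files fail
#' validation here, before any computation. Parameter defaults mirror the
#' analysis the package implements: 150 bp read extension, 2 kb flanks with
#' 100/300/100 bins, pseudocount 0.5, FDR 0.05, fold change 2, spike-in
#' normalization.
#'
#' @param x YAML path or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  cfg$params <- utils::modifyList(default_params(),
                                  if (is.null(cfg$params)) list() else
                                    cfg$params)
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$synthetic)) {
    for (f in c("gtf", "expression")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        stop("config error: ", f, " file not found: ", cfg[[f]])
      }
    }
    for (nm in names(cfg$tracks)) {
      if (!file.exists(cfg$tracks[[nm]])) {
        stop("config error: track file not found: ", cfg$tracks[[nm]])
      }
    }
    for (nm in names(cfg$peaks)) {
      if (!file.exists(cfg$peaks[[nm]])) {
        stop("config error: peak file not found: ", cfg$peaks[[nm]])
      }
    }
    for (p in unlist(cfg$events)) {
      if (!file.exists(p)) stop("config error: event file not found: ", p)
    }
    if (is.null(cfg$gtf)) stop("config error: gtf is required")
    if (length(cfg$tracks) == 0) {
      stop("config error: at least one track is required")
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

run_stage <- function(name, expr) {
  message("[", name, "] ...")
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message("[", name, "] done in ",
          format(round(as.numeric(Sys.time() - t0, units = "secs"), 2)), "s")
  out
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages end to end: annotation loading (or synthesis),
#' gene/transcript selection, track normalization, metagene profiles with
#' body skew, pooled and per-transcript exon/intron enrichment, peak feature
#' distribution, expression stratification with gene-body signal summaries,
#' and splicing-direction enrichment aggregates. Per-condition TSV outputs
#' and a JSON run manifest are written under `out_dir`; outputs are
#' deterministic for a fixed config and seed. Progress goes to stderr.
#'
#' @param cfg a [pipeline_config] (or YAML path / list coercible to one).
#' @return invisible list with all in-memory results and output paths.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- bin_scheme(p$flank, p$flank_bins, p$body_bins)
  synth <- !is.null(cfg$synthetic)

  if (synth) {
    gen <- run_stage("synthesize", {
      gspec <- do.call(synth_genome_spec,
                       utils::modifyList(list(seed = cfg$seed),
                                         if (is.null(cfg$synthetic$genome))
                                           list() else cfg$synthetic$genome))
      generate_annotation(gspec)
    })
    ann <- gen$annotation
    expr_tab <- generate_expression(ann, seed = cfg$seed + 1)$expression
    conditions <- cfg$synthetic$conditions
    if (is.null(conditions)) conditions <- list(default = list())
    tracks <- list(); summaries <- list()
    for (k in seq_along(conditions)) {
      nm <- names(conditions)[k]
      sspec <- do.call(signal_spec,
                       utils::modifyList(list(seed = cfg$seed + 10 + k),
                                         conditions[[k]]))
      covk <- run_stage(paste0("coverage:", nm),
                        generate_coverage(ann, sspec, expression = expr_tab,
                                          ext = p$ext))
      tracks[[nm]] <- normalize_track(covk$track, covk$summary, p$mode)
      summaries[[nm]] <- covk$summary
    }
    peaks <- NULL
    n_coding <- sum(ann$genes$biotype == "protein_coding")
    ev_cfg <- utils::modifyList(
      list(n_up = max(1, floor(n_coding * 0.15)),
           n_down = max(1, floor(n_coding * 0.15)),
           n_null = max(1, floor(n_coding * 0.3))),
      if (is.null(cfg$synthetic$events)) list() else cfg$synthetic$events)
    events <- generate_events(ann, n_up = ev_cfg$n_up,
                              n_down = ev_cfg$n_down,
                              n_null = ev_cfg$n_null,
                              seed = cfg$seed + 2)$events
  } else {
    ann <- run_stage("annotation", read_gtf(cfg$gtf, cfg$chrom_sizes))
    tracks <- run_stage("tracks", {
      lapply(cfg$tracks, read_bedgraph, chrom_sizes = ann$chrom_sizes,
             tag = "raw")
    })
    summaries <- NULL
    expr_tab <- if (is.null(cfg$expression)) NULL else
      read_expression_table(cfg$expression)
    peaks <- if (length(cfg$peaks) > 0) lapply(cfg$peaks, read_bed) else NULL
    events <- if (length(cfg$events) > 0)
      read_rmats_events(unlist(cfg$events)) else NULL
  }

  sel <- run_stage("selection", {
    list(genes = select_metagene_genes(ann, flank = p$flank),
         transcripts = select_exon_transcripts(ann))
  })

  out <- list(annotation = ann, selection = sel, tracks = tracks,
              profiles = list(), skews = list(), global_enrichment = list(),
              scores = list(), strata_summaries = list(),
              as_aggregates = list(), feature_distributions = list())
  paths <- character(0)

  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    prof <- run_stage(paste0("metagene:", nm),
                      metagene_profile(tr, sel$genes, scheme))
    out$profiles[[nm]] <- prof
    out$skews[[nm]] <- body_skew(prof, eps = p$eps)
    f <- file.path(cfg$out_dir, paste0("metagene_", nm, ".tsv"))
    write_metagene_tsv(prof, f)
    paths <- c(paths, f)

    enr <- run_stage(paste0("exon_intron:", nm), {
      list(global = global_exon_intron_signal(
             tr, ann, sel$transcripts$transcript_id),
           scores = per_transcript_enrichment(
             tr, ann, sel$transcripts$transcript_id))
    })
    out$global_enrichment[[nm]] <- enr$global
    out$scores[[nm]] <- enr$scores
    f <- file.path(cfg$out_dir, paste0("enrichment_", nm, ".tsv"))
    utils::write.table(enr$scores, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)

    if (!is.null(expr_tab)) {
      strat <- run_stage(paste0("expression:", nm), {
        gbs <- gene_body_signal(tr, ann$genes)
        rows <- list()
        for (bt in intersect(unique(expr_tab$biotype), names(TPM_CUTOFFS))) {
          s <- stratify_by_expression(expr_tab, bt)
          for (lvl in c("low", "high")) {
            x <- gbs$mean_signal[gbs$gene_id %in% s[[lvl]]]
            if (length(x) == 0) next
            b <- boxplot_summary(x)
            rows[[paste(bt, lvl)]] <- tibble::tibble(
              biotype = bt, stratum = lvl, n = b$n, median = b$median,
              q1 = b$q1, q3 = b$q3, whisker_low = b$whisker_low,
              whisker_high = b$whisker_high,
              n_outliers = length(b$outliers))
          }
        }
        dplyr::bind_rows(rows)
      })
      out$strata_summaries[[nm]] <- strat
      f <- file.path(cfg$out_dir, paste0("expression_strata_", nm, ".tsv"))
      utils::write.table(strat, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, f)
    }

    if (!is.null(events)) {
      agg <- run_stage(paste0("splicing:", nm), {
        sig_ev <- filter_significant(events, fdr_max = p$fdr_max)
        sets <- splice_event_gene_sets(sig_ev)
        aggregate_enrichment(
          out$scores[[nm]],
          list(Up = sets$Up, Down = sets$Down,
               All = unique(out$scores[[nm]]$gene_id)))
      })
      out$as_aggregates[[nm]] <- agg
      f <- file.path(cfg$out_dir, paste0("splicing_enrichment_", nm, ".tsv"))
      utils::write.table(agg, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, f)
    }
  }

  if (!is.null(peaks)) {
    idx <- run_stage("feature_index", build_feature_index(ann))
    for (nm in names(peaks)) {
      dist <- run_stage(paste0("features:", nm),
                        feature_distribution(peaks[[nm]], idx))
      out$feature_distributions[[nm]] <- dist
      f <- file.path(cfg$out_dir, paste0("feature_distribution_", nm,
                                         ".tsv"))
      utils::write.table(dist, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, f)
    }
  }

  manifest <- list(
    package = "chromprofiler",
    version = as.character(utils::packageVersion("chromprofiler")),
    seed = cfg$seed, params = p,
    conditions = names(tracks),
    n_genes_selected = nrow(sel$genes),
    n_transcripts_selected = nrow(sel$transcripts),
    outputs = basename(paths)
  )
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  out$paths <- c(paths, mf)
  invisible(out)
}
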