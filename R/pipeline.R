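# End-to-end pipeline: simulate (or accept) a cohort, segment, discover
# frequent-gain regions, subtract CNPs, integrate with expression, detect
# high-amplitude amplicons, prioritise candidates, and write artifacts with
# a run manifest.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. `cohort` defines the synthetic cohort
#' to generate when no pre-computed data is passed to [run_pipeline()].
#'
#' @param cohort A [cohort_config()] (or NULL when data is supplied).
#' @param cbs A [cbs_params()].
#' @param thresholds A [state_thresholds()].
#' @param min_freq Recurrent-gain frequency threshold (inclusive).
#' @param cnp_freq Germline CNP population-frequency threshold (strict).
#' @param gain_group_cutoff Copy number a sample must exceed to enter the
#'   gain (G) group of a region.
#' @param neutral_range Inclusive copy-number band for the neutral (N) group.
#' @param priority A [priority_config()].
#' @param sigma_e Expression noise sd for the simulated cohort.
#' @param flank Gene flank in bp for copy-number extraction.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory (NULL: nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), cbs = cbs_params(),
                            thresholds = state_thresholds(), min_freq = 0.40,
                            cnp_freq = 0.05, gain_group_cutoff = 3.0,
                            neutral_range = c(1.5, 2.5),
                            priority = priority_config(), sigma_e = 0.3,
                            flank = 1e4, seed = 1L, out_dir = NULL) {
  stop_if(min_freq <= 0 || min_freq > 1, "min_freq must be in (0, 1]")
  stop_if(cnp_freq <= 0 || cnp_freq >= 1, "cnp_freq must be in (0, 1)")
  stop_if(sigma_e < 0, "sigma_e must be >= 0")
  structure(list(cohort = cohort, cbs = cbs, thresholds = thresholds,
                 min_freq = min_freq, cnp_freq = cnp_freq,
                 gain_group_cutoff = gain_group_cutoff,
                 neutral_range = neutral_range, priority = priority,
                 sigma_e = sigma_e, flank = flank, seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The document may set any [pipeline_config()] argument; nested sections
#' `cohort`, `cbs`, `thresholds` and `priority` take the corresponding
#' constructor arguments (`cohort$driver_amplicons` and `cohort$cnp_spec`
#' as lists of field sets). Unknown keys are rejected.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    stop_if(!requireNamespace("yaml", quietly = TRUE),
            "yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(doc), known)
  stop_if(length(bad), "unknown config keys: ", paste(bad, collapse = ", "))
  build <- function(section, fn) {
    if (is.null(doc[[section]])) return(NULL)
    args <- doc[[section]]
    bad <- setdiff(names(args), names(formals(fn)))
    stop_if(length(bad), "unknown ", section, " keys: ",
            paste(bad, collapse = ", "))
    args
  }
  args <- doc
  ca <- build("cohort", cohort_config)
  if (!is.null(ca)) {
    if (!is.null(ca$driver_amplicons)) {
      ca$driver_amplicons <- lapply(ca$driver_amplicons, function(a) {
        do.call(planted_amplicon, a)
      })
    }
    if (!is.null(ca$cnp_spec)) {
      ca$cnp_spec <- lapply(ca$cnp_spec, function(a) do.call(planted_cnp, a))
    }
    if (!is.null(ca$chrom_lengths)) ca$chrom_lengths <- unlist(ca$chrom_lengths)
    if (!is.null(ca$histotypes)) ca$histotypes <- unlist(ca$histotypes)
    args$cohort <- do.call(cohort_config, ca)
  }
  for (sec in c(cbs = "cbs", thresholds = "thresholds")) {
    a <- build(sec, get(if (sec == "cbs") "cbs_params" else "state_thresholds"))
    if (!is.null(a)) {
      args[[sec]] <- do.call(if (sec == "cbs") cbs_params else state_thresholds, a)
    }
  }
  pa <- build("priority", priority_config)
  if (!is.null(pa)) {
    if (!is.null(pa$per_chrom_freq)) pa$per_chrom_freq <- unlist(pa$per_chrom_freq)
    args$priority <- do.call(priority_config, pa)
  }
  do.call(pipeline_config, args)
}

#' Run the full integration pipeline
#'
#' Stage order: simulate (unless `data` is given) -> segment tumours ->
#' call states -> per-sample burden summary -> gain-frequency track ->
#' frequent-gain regions -> cytoband collapsing -> CNP detection from
#' normals and subtraction (each surviving fragment's gain frequency is
#' re-checked and recorded) -> per-region moderated-t differential
#' expression and CN/expression correlation -> high-amplitude amplicon
#' detection -> two-branch prioritisation with rule-replay audit. All
#' randomness derives from `config$seed` (and the cohort's own seed), so a
#' repeated run is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param data Optional pre-built cohort: list with `tumour_markers`,
#'   `normal_markers`, `expr`, `probe_map`, `genes`, `histotype`, and
#'   optionally `cytobands` and `truth`.
#' @return list with per-stage artifacts: `segments`, `profile_summary`,
#'   `track`, `regions_raw`, `cnps`, `regions` (post-subtraction, with
#'   `passes_freq_post_split`), `integration`, `high_amp`, `gene_stats`,
#'   `candidates`, `audit_ok`, `stage_log`, `manifest`, plus the simulated
#'   `cohort` when one was generated.
#' @export
run_pipeline <- function(config, data = NULL) {
  stop_if(!inherits(config, "pipeline_config"), "config must be a pipeline_config")
  warnings_seen <- character()
  log_rows <- list()
  note <- function(stage, metric, value) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      stage = stage, metric = metric, value = value, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  cohort <- NULL
  if (is.null(data)) {
    stop_if(is.null(config$cohort), "config$cohort needed when no data given")
    cohort <- run_stage("simulate", {
      sim <- simulate_cohort(config$cohort)
      ex <- simulate_expression(sim, sim$truth, sigma_e = config$sigma_e,
                                seed = child_seed(config$seed, 1L))
      c(sim, ex)
    })
    data <- list(tumour_markers = cohort$tumour_markers,
                 normal_markers = cohort$normal_markers,
                 expr = cohort$expr, probe_map = cohort$probe_map,
                 genes = cohort$truth$genes,
                 histotype = cohort$truth$histotype,
                 cytobands = make_cytobands(config$cohort$chrom_lengths),
                 truth = cohort$truth)
    note("simulate", "n_tumours", length(unique(data$tumour_markers$sample)))
    note("simulate", "n_normals",
         length(unique(data$normal_markers$sample)))
  }
  stop_if(is.null(data$cytobands), "data$cytobands required")

  segments <- run_stage("segment", {
    call_state(segment_profiles(data$tumour_markers, config$cbs,
                                seed = child_seed(config$seed, 2L)),
               config$thresholds)
  })
  n_tumours <- length(unique(segments$sample))
  note("segment", "n_segments", nrow(segments))

  profile_summary <- run_stage("summarise", summarise_profile(segments))

  track <- run_stage("frequency", {
    build_frequency_track(segments, n_samples = n_tumours)
  })
  regions_raw <- run_stage("regions", {
    collapse_by_cytoband(frequent_gain_regions(track, config$min_freq),
                         data$cytobands)
  })
  note("regions", "n_regions_pre_cnp", nrow(regions_raw))

  cnps <- run_stage("cnp", {
    if (is.null(data$normal_markers) || !nrow(data$normal_markers)) {
      .empty_cnps()
    } else {
      detect_cnps(data$normal_markers, cnp_freq = config$cnp_freq,
                  cbs = config$cbs, thresholds = config$thresholds,
                  seed = child_seed(config$seed, 3L))
    }
  })
  note("cnp", "n_cnps", nrow(cnps))

  regions <- run_stage("cnp_subtract", {
    reg <- subtract_cnps(regions_raw, cnps)
    if (nrow(reg)) {
      # re-check each surviving fragment's gain frequency
      reg$passes_freq_post_split <- vapply(seq_len(nrow(reg)), function(r) {
        tv <- track[track$chrom == reg$chrom[r] & track$start < reg$end[r] &
                      track$end > reg$start[r], , drop = FALSE]
        nrow(tv) > 0 &&
          max(tv$gain_count / tv$n_samples) >= config$min_freq
      }, logical(1))
    } else {
      reg$passes_freq_post_split <- logical(0)
    }
    reg
  })
  note("cnp_subtract", "n_regions_post_cnp", nrow(regions))
  note("cnp_subtract", "n_regions_passing", sum(regions$passes_freq_post_split))

  testable <- regions[regions$passes_freq_post_split, , drop = FALSE]
  integration <- run_stage("integrate", {
    stop_if(!nrow(testable), "no regions survive CNP subtraction")
    integrate_regions(testable, segments, data$expr, data$probe_map,
                      data$genes, histotype = data$histotype,
                      gain_cutoff = config$gain_group_cutoff,
                      neutral_range = config$neutral_range,
                      flank = config$flank)
  })
  note("integrate", "n_probesets_tested", nrow(integration$results))
  note("integrate", "n_regions_skipped", nrow(integration$skipped))

  high_amp <- run_stage("high_amp", {
    high_amplitude_regions(segments, amp_cn = config$priority$branchB$amp_cn,
                           amp_support = config$priority$branchB$amp_support)
  })
  note("high_amp", "n_high_amp_regions", nrow(high_amp))
  ha_genes <- genes_in_high_amp(high_amp, data$genes,
                                flank = config$priority$gene_flank)

  gene_stats <- run_stage("gene_stats", {
    gs <- collapse_probesets(integration$results)
    # high-amplitude genes outside every frequent region still need their
    # copy-number/expression correlation for branch B
    extra <- setdiff(ha_genes, gs$gene)
    if (length(extra)) {
      cn_samples <- intersect(colnames(data$expr),
                              colnames(integration$gene_cn))
      add <- do.call(rbind, lapply(extra, function(g) {
        ps <- data$probe_map$probeset[data$probe_map$gene == g]
        if (!length(ps)) return(NULL)
        rr <- vapply(ps, function(p) {
          cn_expr_correlation(data$expr[p, cn_samples],
                              integration$gene_cn[g, cn_samples])$r
        }, numeric(1))
        data.frame(gene = g, chrom = data$genes$chrom[data$genes$gene == g],
                   p_adj = NA_real_, logFC = NA_real_,
                   r = if (all(is.na(rr))) NA_real_ else max(rr, na.rm = TRUE),
                   stringsAsFactors = FALSE)
      }))
      gs <- rbind(gs, add)
    }
    gs
  })

  gain_freq <- gene_gain_frequency(integration$gene_cn,
                                   gain_cutoff = config$thresholds$gain_cutoff,
                                   n_samples = n_tumours)
  candidates <- run_stage("prioritise", {
    prioritise(gene_stats, gain_freq, ha_genes, config$priority)
  })
  audit_ok <- audit_candidates(candidates)
  note("prioritise", "n_branchA", sum(candidates$branchA))
  note("prioritise", "n_branchB", sum(candidates$branchB))
  note("prioritise", "n_final", sum(candidates$final))

  stage_log <- do.call(rbind, log_rows)
  result <- list(segments = segments, profile_summary = profile_summary,
                 track = track, regions_raw = regions_raw, cnps = cnps,
                 regions = regions, integration = integration,
                 high_amp = high_amp, gene_stats = gene_stats,
                 gain_freq = gain_freq, candidates = candidates,
                 audit_ok = audit_ok, stage_log = stage_log,
                 cohort = cohort)
  result$manifest <- .run_manifest(config, stage_log, warnings_seen)
  if (!is.null(config$out_dir)) .write_artifacts(result, config)
  result
}

.run_manifest <- function(config, stage_log, warnings_seen) {
  cfg_json <- jsonlite::toJSON(.config_doc(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  on.exit(unlink(tmp))
  list(config_hash = unname(tools::md5sum(tmp)),
       package_version = as.character(utils::packageVersion("cnadriver")),
       seed = config$seed,
       counts = setNames(as.list(stage_log$value),
                         paste(stage_log$stage, stage_log$metric, sep = ".")),
       warnings = warnings_seen,
       timestamp = format(Sys.time(), tz = "UTC"))
}

.config_doc <- function(config) {
  doc <- unclass(config)
  doc$out_dir <- NULL # paths do not affect the scientific configuration
  doc$cohort <- if (is.null(doc$cohort)) NULL else {
    co <- unclass(doc$cohort)
    co$driver_amplicons <- lapply(co$driver_amplicons, unclass)
    co$cnp_spec <- lapply(co$cnp_spec, unclass)
    co
  }
  doc$cbs <- unclass(doc$cbs)
  doc$thresholds <- unclass(doc$thresholds)
  doc$priority <- unclass(doc$priority)
  doc
}

.write_artifacts <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_seg(result$segments, p("segments.seg"))
  wt <- function(df, f, comment) {
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    con <- file(p(f), "w")
    on.exit(close(con))
    writeLines(comment, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(result$profile_summary, "profile_summary.tsv",
     "# per-sample alteration burden; fractions of profiled bp")
  wt(result$track, "frequency_track.tsv",
     "# gain/loss sample counts per interval; 0-based half-open bp")
  wt(result$regions_raw, "regions_pre_cnp.tsv",
     "# cytoband-collapsed frequent-gain regions before CNP subtraction; 0-based half-open bp")
  wt(result$cnps, "cnps.tsv",
     "# germline CNP calls from normals; 0-based half-open bp")
  wt(result$regions, "regions.tsv",
     "# candidate regions after CNP subtraction; 0-based half-open bp")
  wt(result$integration$results, "integration.tsv",
     "# per-region probeset statistics: logFC log2(G)-log2(N); r Pearson CN~expression")
  wt(result$high_amp, "high_amplitude_regions.tsv",
     "# intervals with copy number >= 5 in >= 5 samples; 0-based half-open bp")
  wt(result$candidates, "candidates.tsv",
     "# prioritised candidate genes with per-criterion flags")
  if (!is.null(result$cohort)) {
    write_markers(result$cohort$tumour_markers, p("tumour_markers.tsv"))
    write_markers(result$cohort$normal_markers, p("normal_markers.tsv"))
    write_expression(result$cohort$expr, p("expression.tsv"))
    write_gene_bed(result$cohort$truth$genes, p("genes.bed"))
    write_sample_sheet(result$cohort$samples, p("samples.tsv"))
    write_truth(result$cohort$truth, p("truth.json"))
    write.table(make_cytobands(config$cohort$chrom_lengths),
                p("cytobands.txt"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
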