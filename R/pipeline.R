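#' Run the full switch-calling pipeline
#'
#' End-to-end orchestration: simulate (or read) probe tracks, median-center,
#' loess-smooth, aggregate into fixed windows, test windows with the
#' empirical-null distance statistic, segment the per-probe unsmoothed dRT
#' into domains, and write the artifact bundle (window TSV, call TSV/BED per
#' cutoff, segment TSV/BED, truth BED, config YAML, JSON summary, log).
#' Deterministic given the config seed: one top-level seed derives the
#' per-stage seeds for simulation and segmentation permutations.
#'
#' The significance test runs on smoothed values by default
#' (`use_smoothed`); segmentation always consumes the normalized,
#' unsmoothed per-probe differential.
#'
#' @param cfg A [default_run_config()]-style `run_config`.
#' @param probes Optional pre-built [probe_matrix()]; when supplied the
#'   simulation stage is skipped and `truth` is unavailable.
#' @return (Invisibly) a list with `probes`, `truth`, `windows`, `calls`
#'   (per cutoff), `segments`, `summary`, `paths`.
#' @export
run_pipeline <- function(cfg, probes = NULL) {
  .validate_run_config(cfg)
  layout <- make_genome_layout(unlist(cfg$genome))
  seeds <- derive_seeds(cfg$seed, 3L)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (is.null(probes)) {
    sc <- do.call(sim_config, c(cfg$sim, list(seed = seeds[1])))
    sim <- simulate_rt_dataset(layout, sc)
    probes <- sim$probes
    truth <- sim$truth
  }
  conditions <- unique(probes$samples$condition)

  norm <- align_conditions(normalize_arrays(probes), conditions)
  smoothed <- loess_smooth(norm, cfg$bandwidth_bp)
  test_pm <- if (isTRUE(cfg$use_smoothed)) smoothed else norm

  primary_cut <- min(cfg$q_cutoffs)
  calls <- switch_test(test_pm, layout, cfg$window_bp,
                       conditions = conditions, q_cutoff = primary_cut,
                       pi0_method = cfg$pi0_method)
  calls_by_cutoff <- lapply(cfg$q_cutoffs, function(qc) {
    call_switches(as.data.frame(calls)[, !(names(calls) %in% "direction")],
                  calls$q, qc)
  })
  names(calls_by_cutoff) <- paste0("q", cfg$q_cutoffs)

  cols <- .condition_columns(norm, conditions)
  drt_probe <- rowMeans(norm$values[, cols[[2]], drop = FALSE]) -
    rowMeans(norm$values[, cols[[1]], drop = FALSE])
  segs <- cbs_segment(norm$chrom, norm$pos, drt_probe,
                      alpha = cfg$segmentation$alpha,
                      min_width = cfg$segmentation$min_width,
                      n_perm = cfg$segmentation$n_perm,
                      merge_tol = cfg$segmentation$merge_tol,
                      seed = seeds[2])
  segs <- classify_segments(segs, cfg$segmentation$class_threshold, layout)

  count_tab <- lapply(calls_by_cutoff, function(ct) {
    cnt <- attr(ct, "counts")
    list(EtoL = unname(cnt["EtoL"]), LtoE = unname(cnt["LtoE"]))
  })
  seg_sizes <- lapply(c("EtoL", "LtoE", "none"), function(cl) {
    sz <- segs$size[segs$class == cl]
    list(class = cl, n = length(sz),
         median_bp = if (length(sz)) stats::median(sz) else NA,
         q1_bp = if (length(sz)) unname(stats::quantile(sz, 0.25)) else NA,
         q3_bp = if (length(sz)) unname(stats::quantile(sz, 0.75)) else NA)
  })
  sample_cols <- probes$samples$sample
  cormat <- pearson_matrix(as.matrix(as.data.frame(calls)[, sample_cols]))

  paths <- list(
    config = file.path(cfg$out_dir, "config.yaml"),
    windows = file.path(cfg$out_dir, "windows.tsv"),
    calls = file.path(cfg$out_dir, "calls.tsv"),
    segments = file.path(cfg$out_dir, "segments.tsv"),
    segments_bed = file.path(cfg$out_dir, "segments.bed"),
    summary = file.path(cfg$out_dir, "summary.json"),
    log = file.path(cfg$out_dir, "run.log"))
  write_run_config(cfg, paths$config)
  write_window_table(as.data.frame(calls)[, c("chrom", "start", "end",
                                              "n_probes", sample_cols,
                                              paste0("mean_", conditions[1:2]),
                                              "dRT")],
                     paths$windows)
  write_window_table(as.data.frame(calls), paths$calls)
  for (i in seq_along(cfg$q_cutoffs)) {
    bed <- file.path(cfg$out_dir,
                     sprintf("calls_q%s.bed", cfg$q_cutoffs[i]))
    write_calls_bed(calls_by_cutoff[[i]], bed)
    paths[[paste0("calls_bed_q", cfg$q_cutoffs[i])]] <- bed
  }
  write_window_table(segs, paths$segments)
  write_segments_bed(segs, paths$segments_bed)
  if (!is.null(truth)) {
    paths$truth <- file.path(cfg$out_dir, "truth.bed")
    write_truth_bed(truth, paths$truth)
  }

  summary <- list(
    seed = cfg$seed,
    n_probes = length(probes$pos),
    n_windows = nrow(calls),
    n_testable = sum(!is.na(calls$p)),
    pi0 = attr(calls, "pi0"),
    calls = count_tab,
    segment_sizes = seg_sizes,
    correlation = list(samples = sample_cols,
                       r = unname(split(round(cormat, 6),
                                        row(cormat))))
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)

  log_lines <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("config_md5: %s", unname(tools::md5sum(paths$config))),
    sprintf("probes: %d", length(probes$pos)),
    sprintf("windows: %d (testable %d)", nrow(calls),
            sum(!is.na(calls$p))),
    sprintf("null_size: %d", attr(calls, "null")$n),
    vapply(seq_along(cfg$q_cutoffs), function(i) {
      cnt <- attr(calls_by_cutoff[[i]], "counts")
      sprintf("calls at q<=%s: EtoL %d, LtoE %d", cfg$q_cutoffs[i],
              cnt["EtoL"], cnt["LtoE"])
    }, ""),
    sprintf("segments: %d", nrow(segs)))
  writeLines(log_lines, paths$log)

  invisible(list(probes = probes, truth = truth, windows = calls,
                 calls = calls_by_cutoff, segments = segs,
                 summary = summary, paths = paths))
}
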