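#' Tile indices overlapping ground-truth switching domains
#'
#' @param truth `sim_truth` data frame (`chrom`, `start`, `end`).
#' @param layout Genome layout.
#' @param window_bp Tile width.
#' @return Integer vector of genome-wide tile indices overlapping any
#'   injected domain.
#' @export
truth_windows <- function(truth, layout, window_bp = 200000L) {
  if (nrow(truth) == 0L) return(integer(0))
  tiles <- genome_tiles(layout, window_bp)
  hits <- logical(nrow(tiles))
  for (i in seq_len(nrow(truth))) {
    hit <- tiles$chrom == truth$chrom[i] & tiles$start < truth$end[i] &
      tiles$end > truth$start[i]
    hits <- hits | hit
  }
  which(hits)
}

#' Evaluate switch calls against simulation ground truth
#'
#' The false-discovery proportion (FDP) counts called windows that do not
#' overlap any injected domain; a run with no calls has FDP 0 by
#' convention. Sensitivity is the fraction of injected domains hit by at
#' least one called window of the matching direction.
#'
#' @param calls A [switch_test()] table (rows aligned to the tile frame).
#' @param truth `sim_truth` data frame.
#' @param layout Genome layout.
#' @param window_bp Tile width.
#' @param q_cutoff Cutoff at which to evaluate (re-thresholds `calls$q`).
#' @return List: `n_called`, `n_false`, `fdp`, `domain_sensitivity`.
#' @export
evaluate_calls <- function(calls, truth, layout, window_bp = 200000L,
                           q_cutoff = attr(calls, "q_cutoff")) {
  called <- which(!is.na(calls$q) & calls$q <= q_cutoff & calls$dRT != 0)
  true_set <- truth_windows(truth, layout, window_bp)
  n_false <- sum(!(called %in% true_set))
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    dir <- truth$direction[i]
    w <- which(calls$chrom == truth$chrom[i] &
                 calls$start < truth$end[i] & calls$end > truth$start[i])
    w <- intersect(w, called)
    any((dir == "EtoL" & calls$dRT[w] < 0) |
          (dir == "LtoE" & calls$dRT[w] > 0))
  }, NA)
  list(n_called = length(called),
       n_false = n_false,
       fdp = if (length(called) > 0) n_false / length(called) else 0,
       domain_sensitivity = if (nrow(truth) > 0) mean(hit) else NA_real_)
}

#' Simulation experiment measuring empirical FDR control
#'
#' Runs the full pipeline (simulate, normalize, smooth, window, empirical
#' null distance test, Storey q-values) on `n_sims` independently seeded
#' synthetic datasets and measures the false-discovery proportion of the
#' window calls at each q-value cutoff against the injected ground truth.
#'
#' @param n_sims Number of simulated datasets.
#' @param base_seed Top-level seed; per-dataset seeds are derived from it.
#' @param layout Genome layout (default two 50-Mb chromosomes).
#' @param config A [sim_config()]; its seed field is overridden per
#'   dataset. Default: the reference design (probes every 5.5 Kb, 2 x 2,
#'   30 injected 400-800 Kb domains, |effect| 1-1.5, probe noise sd 0.35).
#' @param q_cutoffs q-value cutoffs to evaluate.
#' @param bandwidth_bp Smoothing bandwidth.
#' @param window_bp Window width.
#' @param pi0_method Passed to [storey_qvalues()].
#' @param use_smoothed Run the distance test on loess-smoothed values
#'   instead of the normalized raw values. Off by default: smoothing bleeds
#'   a true domain's signal up to half a bandwidth past its edges, so
#'   windows bordering a real switch acquire genuine (leaked) signal and
#'   are counted as false discoveries against the sharp ground truth.
#' @return Data frame with one row per dataset x cutoff: `seed`, `q_cutoff`,
#'   `n_called`, `n_false`, `fdp`, `domain_sensitivity`.
#' @export
switch_fdr_experiment <- function(n_sims = 20L, base_seed = 1L,
                                  layout = make_genome_layout(
                                    c(chr1 = 5e7, chr2 = 5e7)),
                                  config = sim_config(n_switch_domains = 30L),
                                  q_cutoffs = c(0.01, 0.05),
                                  bandwidth_bp = 300000,
                                  window_bp = 200000L,
                                  pi0_method = "smoother",
                                  use_smoothed = FALSE) {
  seeds <- derive_seeds(base_seed, n_sims)
  rows <- list()
  for (s in seeds) {
    config$seed <- as.integer(s)
    sim <- simulate_rt_dataset(layout, config)
    pm <- align_conditions(normalize_arrays(sim$probes))
    if (use_smoothed) pm <- loess_smooth(pm, bandwidth_bp)
    calls <- switch_test(pm, layout, window_bp,
                         conditions = config$conditions,
                         q_cutoff = max(q_cutoffs), pi0_method = pi0_method)
    for (qc in q_cutoffs) {
      ev <- evaluate_calls(calls, sim$truth, layout, window_bp,
                           q_cutoff = qc)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, q_cutoff = qc, n_called = ev$n_called,
        n_false = ev$n_false, fdp = ev$fdp,
        domain_sensitivity = ev$domain_sensitivity)
    }
  }
  do.call(rbind, rows)
}
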