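#' Default end-to-end run configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]:
#' genome spec, simulation parameters, processing parameters (window size,
#' smoothing bandwidth), significance and segmentation settings, and the
#' top-level seed from which all per-stage seeds are derived. Serializes
#' losslessly to/from YAML.
#'
#' @param seed Top-level seed.
#' @param out_dir Output directory for run artifacts.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "rtswitch_run") {
  cfg <- list(
    genome = list(chr1 = 5e7, chr2 = 5e7),
    sim = list(probe_spacing = 5500, n_replicates = 2L,
               conditions = c("control", "treatment"),
               baseline_domain_bp = c(8e5, 2e6),
               baseline_rt_range = c(-2.5, 2.5),
               n_switch_domains = 30L,
               switch_size_bp = c(4e5, 8e5),
               switch_effect_range = c(1.0, 1.5),
               switch_direction_mix = 0.5,
               probe_noise_sd = 0.35,
               replicate_offset_sd = 0.1),
    window_bp = 200000L,
    bandwidth_bp = 300000L,
    use_smoothed = FALSE,
    q_cutoffs = c(0.01, 0.05),
    pi0_method = "smoother",
    segmentation = list(alpha = 0.01, min_width = 5L, n_perm = 1000L,
                        merge_tol = 0.1, class_threshold = 0.5),
    overlap_n_perm = 999L,
    seed = as.integer(seed),
    out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

.validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg$genome), length(cfg$genome) >= 1L,
            all(unlist(cfg$genome) > 0),
            cfg$window_bp > 0, cfg$bandwidth_bp > 0,
            all(cfg$q_cutoffs > 0 & cfg$q_cutoffs < 1),
            cfg$segmentation$alpha > 0, cfg$segmentation$alpha < 1,
            cfg$segmentation$min_width >= 2,
            cfg$segmentation$n_perm >= 1,
            cfg$overlap_n_perm >= 1)
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in names(base)) if (is.null(cfg[[nm]])) cfg[[nm]] <- base[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$sim$n_replicates <- as.integer(cfg$sim$n_replicates)
  cfg$sim$n_switch_domains <- as.integer(cfg$sim$n_switch_domains)
  class(cfg) <- "run_config"
  .validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg A `run_config` list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
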