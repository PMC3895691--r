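#' Simulation configuration for synthetic replication-timing data
#'
#' Bundles the parameters of the two-condition, replicated Repli-chip style
#' generator. The defaults describe the reference simulation design used
#' throughout the package: a uniform probe grid every 5.5 Kb, two biological
#' replicates per condition, a piecewise-constant baseline timing landscape
#' of 0.8-2 Mb domains spanning roughly -2.5 to +2.5 log2(early/late) units,
#' injected switching domains of 400-800 Kb, and two Gaussian noise scales
#' (a global per-sample replicate offset plus i.i.d. probe noise).
#'
#' Sign convention: values are log2(early/late), so higher means earlier
#' replication. An early-to-late (EtoL) switch in the second condition has a
#' negative injected effect; late-to-early (LtoE) a positive one.
#'
#' @param probe_spacing Probe spacing in bp (uniform grid).
#' @param n_replicates Biological replicates per condition (>= 2; the
#'   within-group empirical null needs replicate pairs).
#' @param conditions Two condition labels; the second receives the injected
#'   switch effects, and dRT is second minus first.
#' @param baseline_domain_bp Length-2 range (bp) of baseline timing domains.
#' @param baseline_rt_range Length-2 range of baseline RT in log2 units.
#' @param n_switch_domains Number of injected switching domains.
#' @param switch_size_bp Length-2 range (bp) of injected domain sizes.
#' @param switch_effect_range Length-2 range of effect magnitudes (log2).
#' @param switch_direction_mix Fraction of injected domains that are EtoL;
#'   realised as an exact count so the two directions stay balanced and
#'   median centering does not pick up a global offset.
#' @param probe_noise_sd Per-probe Gaussian noise sd (log2 units).
#' @param replicate_offset_sd Sd of the single global additive offset drawn
#'   per sample (log2 units).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(probe_spacing = 5500,
                       n_replicates = 2L,
                       conditions = c("control", "treatment"),
                       baseline_domain_bp = c(8e5, 2e6),
                       baseline_rt_range = c(-2.5, 2.5),
                       n_switch_domains = 0L,
                       switch_size_bp = c(4e5, 8e5),
                       switch_effect_range = c(1.0, 1.5),
                       switch_direction_mix = 0.5,
                       probe_noise_sd = 0.35,
                       replicate_offset_sd = 0.1,
                       seed = 1L) {
  cfg <- list(probe_spacing = probe_spacing,
              n_replicates = as.integer(n_replicates),
              conditions = as.character(conditions),
              baseline_domain_bp = as.numeric(baseline_domain_bp),
              baseline_rt_range = as.numeric(baseline_rt_range),
              n_switch_domains = as.integer(n_switch_domains),
              switch_size_bp = as.numeric(switch_size_bp),
              switch_effect_range = as.numeric(switch_effect_range),
              switch_direction_mix = switch_direction_mix,
              probe_noise_sd = probe_noise_sd,
              replicate_offset_sd = replicate_offset_sd,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is.finite(probe_spacing) || probe_spacing <= 0) {
      stop("probe_spacing must be positive")
    }
    if (n_replicates < 2L) stop("n_replicates must be >= 2")
    if (length(conditions) != 2L || anyDuplicated(conditions)) {
      stop("exactly two distinct condition labels are required")
    }
    for (rng in list(baseline_domain_bp, switch_size_bp)) {
      if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2]) {
        stop("size ranges must be positive and ordered (low, high)")
      }
    }
    if (baseline_rt_range[1] > baseline_rt_range[2]) {
      stop("baseline_rt_range must be ordered")
    }
    if (n_switch_domains < 0L) stop("n_switch_domains must be >= 0")
    if (any(switch_effect_range <= 0) ||
        switch_effect_range[1] > switch_effect_range[2]) {
      stop("switch_effect_range must be positive and ordered")
    }
    if (switch_direction_mix < 0 || switch_direction_mix > 1) {
      stop("switch_direction_mix must be in [0, 1]")
    }
    if (probe_noise_sd < 0 || replicate_offset_sd < 0) {
      stop("noise sds must be >= 0")
    }
  })
  invisible(cfg)
}

# Piecewise-constant baseline RT landscape for one chromosome: domain
# lengths drawn uniformly from the configured range until the chromosome is
# covered, one RT level per domain.
.baseline_domains <- function(len, cfg) {
  starts <- numeric(0)
  ends <- numeric(0)
  at <- 0
  while (at < len) {
    d <- stats::runif(1, cfg$baseline_domain_bp[1], cfg$baseline_domain_bp[2])
    starts <- c(starts, at)
    ends <- c(ends, min(at + d, len))
    at <- at + d
  }
  data.frame(start = starts, end = ends,
             rt = stats::runif(length(starts), cfg$baseline_rt_range[1],
                               cfg$baseline_rt_range[2]))
}

# Place n non-overlapping switch domains on the layout, chromosomes chosen
# proportional to length, bounded retries.
.place_switch_domains <- function(layout, cfg, max_tries = 1000L) {
  n <- cfg$n_switch_domains
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE))
  }
  n_etol <- round(cfg$switch_direction_mix * n)
  direction <- c(rep("EtoL", n_etol), rep("LtoE", n - n_etol))
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      size <- stats::runif(1, cfg$switch_size_bp[1], cfg$switch_size_bp[2])
      ci <- sample.int(nrow(layout), 1L, prob = layout$length)
      len <- layout$length[ci]
      if (len <= size) next
      start <- stats::runif(1, 0, len - size)
      end <- start + size
      same <- placed$chrom == layout$chrom[ci]
      if (!any(same & placed$start < end & placed$end > start)) {
        placed <- rbind(placed, data.frame(chrom = layout$chrom[ci],
                                           start = start, end = end,
                                           stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", n, " non-overlapping switch domains; ",
           "reduce the count or enlarge the genome")
    }
  }
  magnitude <- stats::runif(n, cfg$switch_effect_range[1],
                            cfg$switch_effect_range[2])
  placed$direction <- direction
  placed$effect <- ifelse(direction == "EtoL", -magnitude, magnitude)
  placed
}

#' Simulate a two-condition replicated replication-timing dataset
#'
#' Builds a piecewise-constant baseline timing landscape shared by both
#' conditions, injects sharp-edged switching domains into the second
#' condition only, and emits per-sample probe values
#' `true RT + replicate offset + probe noise` on a uniform probe grid.
#' Fully deterministic given `config$seed`.
#'
#' @param layout A [make_genome_layout()] object.
#' @param config A [sim_config()] object.
#' @param truth Optional pre-existing `sim_truth` to re-use (its domains are
#'   injected instead of drawing new ones), giving independently noised
#'   datasets that share one ground truth.
#' @return List with elements `probes` (a [probe_matrix()]) and `truth`
#'   (a `sim_truth` data frame of injected domains: `chrom`, `start`, `end`,
#'   `direction`, `effect`, with the seed as attribute).
#' @export
simulate_rt_dataset <- function(layout, config, truth = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  .validate_sim_config(config)
  set.seed(config$seed)

  chrom <- character(0); pos <- numeric(0); base_rt <- numeric(0)
  for (i in seq_len(nrow(layout))) {
    p <- seq(0, layout$length[i] - 1, by = config$probe_spacing)
    dom <- .baseline_domains(layout$length[i], config)
    idx <- findInterval(p, dom$start)
    chrom <- c(chrom, rep(layout$chrom[i], length(p)))
    pos <- c(pos, p)
    base_rt <- c(base_rt, dom$rt[idx])
  }

  if (is.null(truth)) truth <- .place_switch_domains(layout, config)
  effect <- numeric(length(pos))
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      hit <- chrom == truth$chrom[i] & pos >= truth$start[i] & pos < truth$end[i]
      effect[hit] <- effect[hit] + truth$effect[i]
    }
  }

  conds <- rep(config$conditions, each = config$n_replicates)
  reps <- rep(seq_len(config$n_replicates), times = 2L)
  samples <- data.frame(sample = paste0(conds, "_r", reps),
                        condition = conds, replicate = reps,
                        stringsAsFactors = FALSE)
  true_rt <- cbind(base_rt, base_rt + effect)[, match(conds, config$conditions)]
  offsets <- stats::rnorm(nrow(samples), 0, config$replicate_offset_sd)
  noise <- matrix(stats::rnorm(length(pos) * nrow(samples), 0,
                               config$probe_noise_sd),
                  nrow = length(pos))
  values <- true_rt + rep(offsets, each = length(pos)) + noise
  colnames(values) <- samples$sample

  pm <- probe_matrix(chrom, pos, values, samples)
  attr(truth, "seed") <- config$seed
  class(truth) <- c("sim_truth", "data.frame")
  list(probes = pm, truth = truth)
}

#' Simulate binding sites whose density follows replication timing
#'
#' Per 200-Kb window, the site count is Poisson with log-linear rate
#' `lambda(w) = exp(a + b * RT(w))`, and site positions are uniform within
#' the window. Emulates a ChIP-seq peak set enriched in early-replicating
#' chromatin when `b > 0`.
#'
#' @param tiles Tile frame from [genome_tiles()] (or a window table) with
#'   columns `chrom`, `start`, `end`.
#' @param rt Numeric window RT vector aligned to `tiles`; windows with
#'   missing RT receive no sites.
#' @param rate_model Length-2 numeric `c(a, b)` of the log-linear rate.
#' @param seed Integer seed.
#' @return A `binding_sites` data frame (`chrom`, `pos`), sorted.
#' @export
simulate_binding_sites <- function(tiles, rt, rate_model, seed = 1L) {
  stopifnot(nrow(tiles) == length(rt), length(rate_model) == 2L)
  lambda <- exp(rate_model[1] + rate_model[2] * rt)
  if (any(!is.finite(lambda[!is.na(rt)]))) {
    stop("non-finite Poisson rate; check rate_model")
  }
  set.seed(as.integer(seed))
  lambda[is.na(lambda)] <- 0
  counts <- stats::rpois(length(lambda), lambda)
  idx <- rep.int(seq_along(counts), counts)
  pos <- stats::runif(length(idx), tiles$start[idx], tiles$end[idx])
  sites <- data.frame(chrom = tiles$chrom[idx], pos = pos,
                      stringsAsFactors = FALSE)
  sites <- sites[order(match(sites$chrom, unique(tiles$chrom)), sites$pos), ]
  rownames(sites) <- NULL
  class(sites) <- c("binding_sites", "data.frame")
  sites
}

#' Simulate gene expression changes independent of timing switches
#'
#' Places genes uniformly over windows and draws log2 fold-changes
#' independently of switch status (Normal(0, `lfc_sd`)); a configurable
#' fraction is flagged as remodeler target genes. This emulates the null
#' relationship between timing switching and transcriptional change.
#'
#' @param tiles Tile frame (`chrom`, `start`, `end`).
#' @param n_genes Number of genes (> 0).
#' @param lfc_sd Sd of the log2 fold-changes.
#' @param prop_target Fraction flagged as targets.
#' @param seed Integer seed.
#' @return An `expression_table` data frame: `gene`, `chrom`, `pos`, `tile`,
#'   `log2fc`, `is_target`.
#' @export
simulate_expression <- function(tiles, n_genes, lfc_sd = 0.5,
                                prop_target = 0.05, seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be > 0")
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(tiles), n_genes, replace = TRUE)
  pos <- stats::runif(n_genes, tiles$start[idx], tiles$end[idx])
  out <- data.frame(gene = sprintf("gene%05d", seq_len(n_genes)),
                    chrom = tiles$chrom[idx], pos = pos, tile = tiles$tile[idx],
                    log2fc = stats::rnorm(n_genes, 0, lfc_sd),
                    is_target = stats::runif(n_genes) < prop_target,
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}
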