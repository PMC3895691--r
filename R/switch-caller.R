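#' Between-group distance over one window's probes
#'
#' RMS-normalized Euclidean distance between the two group-mean probe
#' vectors of a window: `sqrt(sum((a_i - b_i)^2) / m)` over the `m` probes
#' with non-missing values in all samples. The 1/m normalization makes
#' windows of unequal probe counts comparable against one pooled null.
#'
#' @param values Numeric matrix, window probes x samples (columns named as
#'   in `samples$sample`).
#' @param samples Sample sheet (`sample`, `condition`, `replicate`).
#' @param conditions Optional length-2 condition labels.
#' @return Non-negative distance, or `NA` when no probe is usable (the
#'   window is untestable).
#' @export
segment_distance <- function(values, samples, conditions = NULL) {
  values <- as.matrix(values)
  pm <- list(samples = samples)
  cols <- .condition_columns(pm, conditions)
  ok <- stats::complete.cases(values)
  if (!any(ok)) return(NA_real_)
  ga <- rowMeans(values[ok, cols[[1]], drop = FALSE])
  gb <- rowMeans(values[ok, cols[[2]], drop = FALSE])
  sqrt(mean((ga - gb)^2))
}

# Windowed RMS of one probe-level contrast vector. With recenter = TRUE the
# contrast's genome-wide median (over usable probes) is subtracted first:
# per-sample median centering cannot remove a residual global offset between
# the conditions when part of the genome genuinely switches, but the median
# of the probe-level *difference* is robust to switching as long as most of
# the genome is unchanged. Applied identically to between-group contrasts
# and within-group null pairs so calibration is preserved.
.contrast_rms <- function(diffvec, ok, idx, n_tiles, m, recenter) {
  if (recenter) diffvec <- diffvec - stats::median(diffvec[ok])
  agg <- rowsum(diffvec[ok]^2, idx[ok])
  ssq <- rep(0, n_tiles)
  ssq[as.integer(rownames(agg))] <- agg[, 1]
  ifelse(m > 0, sqrt(ssq / pmax(m, 1L)), NA_real_)
}

# Per-window distances for a whole probe matrix, aligned to the tile frame.
# Internal core shared by switch_test(); uses the same complete-probe mask
# and RMS normalization as segment_distance().
.window_distances <- function(pm, layout, window_bp, conditions,
                              recenter = TRUE) {
  tiles <- genome_tiles(layout, window_bp)
  idx <- .tile_index(pm$chrom, pm$pos, layout, window_bp)
  cols <- .condition_columns(pm, conditions)
  ok <- stats::complete.cases(pm$values)
  ga <- rowMeans(pm$values[, cols[[1]], drop = FALSE])
  gb <- rowMeans(pm$values[, cols[[2]], drop = FALSE])
  m <- tabulate(idx[ok], nbins = nrow(tiles))
  dist <- .contrast_rms(ga - gb, ok, idx, nrow(tiles), m, recenter)
  list(tiles = tiles, idx = idx, ok = ok, distance = dist, m = m,
       cols = cols)
}

#' Pooled within-group empirical null distribution
#'
#' For every testable window and every unordered within-group replicate
#' pair, computes the RMS-normalized distance between the two replicate
#' probe vectors and pools the distances genome-wide (across all windows and
#' both groups) into a single null multiset.
#'
#' By default each pair distance is rescaled by
#' `sqrt((1/nA + 1/nB) / 2)` so that, under the exchangeable Gaussian null,
#' it matches the sampling distribution of the between-group mean contrast
#' tested by [segment_distance()] (a replicate difference has variance
#' `2 sigma^2` per probe, the difference of group means
#' `sigma^2 (1/nA + 1/nB)`). Set `scale_to_contrast = FALSE` for the raw
#' (stochastically larger, hence conservative) pair distances.
#'
#' @param pm A [probe_matrix()] (typically normalized + smoothed).
#' @param layout Genome layout.
#' @param window_bp Window width in bp.
#' @param conditions Optional length-2 condition labels.
#' @param scale_to_contrast Apply the variance-matching scale factor.
#' @param recenter Subtract each contrast vector's genome-wide median
#'   before windowing (see [switch_test()]).
#' @return A `null_distribution` list: `distances`, `n`, `scale`.
#' @export
build_null <- function(pm, layout, window_bp = 200000L, conditions = NULL,
                       scale_to_contrast = TRUE, recenter = TRUE) {
  stopifnot(inherits(pm, "probe_matrix"))
  wd <- .window_distances(pm, layout, window_bp, conditions, recenter)
  cols <- wd$cols
  n_a <- length(cols[[1]]); n_b <- length(cols[[2]])
  if (n_a < 2L || n_b < 2L) {
    stop("each group needs >= 2 replicates to build the empirical null")
  }
  scale <- if (scale_to_contrast) sqrt((1 / n_a + 1 / n_b) / 2) else 1
  testable <- wd$m > 0
  pool <- numeric(0)
  for (g in seq_along(cols)) {
    reps <- cols[[g]]
    prs <- utils::combn(reps, 2L)
    for (k in seq_len(ncol(prs))) {
      dv <- pm$values[, prs[1, k]] - pm$values[, prs[2, k]]
      d <- .contrast_rms(dv, wd$ok, wd$idx, length(wd$m), wd$m,
                         recenter) * scale
      pool <- c(pool, d[testable])
    }
  }
  structure(list(distances = pool, n = length(pool), scale = scale),
            class = "null_distribution")
}

#' Empirical right-tail p-values against a pooled null
#'
#' Add-one estimator `p = (1 + #\{null >= d\}) / (1 + n)`, with ties counted
#' inclusively; `p` is always in (0, 1], never exactly zero, as required by
#' the q-value machinery downstream.
#'
#' @param distances Observed window distances (`NA` passes through).
#' @param null A [build_null()] object (or numeric vector of null
#'   distances).
#' @return p-value vector aligned with `distances`.
#' @export
empirical_pvalues <- function(distances, null) {
  nd <- if (inherits(null, "null_distribution")) null$distances else
    as.numeric(null)
  if (length(nd) < 1L) stop("empty null distribution")
  sn <- sort(nd)
  n <- length(sn)
  cnt_ge <- n - findInterval(distances, sn, left.open = TRUE)
  p <- (1 + cnt_ge) / (1 + n)
  p[is.na(distances)] <- NA_real_
  p
}

#' Storey q-values
#'
#' Converts p-values to q-values by the Storey procedure: the proportion of
#' true nulls pi0 is estimated on the lambda grid 0, 0.05, ..., 0.90 with a
#' cubic smoothing spline evaluated at the largest lambda (falling back to
#' the conservative pi0 = 1 whenever the spline estimate leaves (0, 1]);
#' then `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` over the sorted p-values.
#' With `pi0_method = "fixed_1"` the result equals Benjamini-Hochberg
#' adjusted p-values exactly.
#'
#' @param p P-values in (0, 1] (`NA` passes through).
#' @param pi0_method `"smoother"` (Storey lambda-grid spline) or
#'   `"fixed_1"` (pi0 = 1, i.e. Benjamini-Hochberg).
#' @return q-value vector with attribute `pi0`.
#' @export
storey_qvalues <- function(p, pi0_method = c("smoother", "fixed_1")) {
  pi0_method <- match.arg(pi0_method)
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0L) stop("no p-values")
  if (any(pv <= 0 | pv > 1)) stop("p-values must be in (0, 1]")
  m <- length(pv)
  pi0 <- 1
  if (pi0_method == "smoother") {
    lambda <- seq(0, 0.90, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
    fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    est <- if (inherits(fit, "try-error")) NA_real_ else
      stats::predict(fit, x = max(lambda))$y
    pi0 <- if (is.finite(est) && est > 0 && est <= 1) est else 1
  }
  o <- order(pv)
  r <- pi0 * m * pv[o] / seq_len(m)
  qs <- rev(cummin(rev(r)))
  q <- rep(NA_real_, length(p))
  q[ok][o] <- qs
  attr(q, "pi0") <- pi0
  q
}

#' Call switching windows at a q-value cutoff
#'
#' A window is called switching when `q <= q_cutoff`; its direction is EtoL
#' when dRT < 0 and LtoE when dRT > 0 (log2(early/late) convention: a
#' negative differential means the second condition replicates later).
#' A called window with dRT exactly 0 stays uncalled with a warning.
#'
#' @param windows A window table (needs a `dRT` column) or data frame
#'   aligned with `q`.
#' @param q q-value vector aligned with the rows of `windows`.
#' @param q_cutoff FDR cutoff in (0, 1).
#' @return `windows` with columns `q` and `direction`
#'   (`"EtoL"`/`"LtoE"`/`"none"`); attribute `counts` holds the
#'   per-direction call counts.
#' @export
call_switches <- function(windows, q, q_cutoff = 0.01) {
  if (!is.numeric(q_cutoff) || q_cutoff <= 0 || q_cutoff >= 1) {
    stop("q_cutoff must be in (0, 1)")
  }
  stopifnot(nrow(windows) == length(q), "dRT" %in% names(windows))
  called <- !is.na(q) & q <= q_cutoff
  direction <- rep("none", nrow(windows))
  direction[called & windows$dRT < 0] <- "EtoL"
  direction[called & windows$dRT > 0] <- "LtoE"
  if (any(called & windows$dRT == 0, na.rm = TRUE)) {
    warning("window(s) significant at the cutoff with dRT exactly 0 ",
            "left uncalled")
  }
  windows$q <- as.numeric(q)
  windows$direction <- direction
  attr(windows, "counts") <- c(EtoL = sum(direction == "EtoL"),
                               LtoE = sum(direction == "LtoE"),
                               none = sum(direction == "none"))
  attr(windows, "q_cutoff") <- q_cutoff
  windows
}

#' Full window-level switch test
#'
#' Convenience wrapper running the whole significance chain on one probe
#' matrix: fixed-window aggregation, between-group RMS Euclidean distances,
#' pooled within-replicate empirical null, add-one right-tail p-values,
#' Storey q-values and the directional call.
#'
#' With `recenter = TRUE` (default) every probe-level contrast vector
#' (the between-group mean difference, and each within-group replicate
#' difference entering the null) has its genome-wide median subtracted
#' before windowing. Per-sample median centering leaves a residual global
#' offset between conditions whenever part of the genome genuinely
#' switches; the median of the probe-level difference is robust to that as
#' long as most of the genome is unchanged, and applying the same
#' recentring to the null pairs preserves calibration.
#'
#' @inheritParams build_null
#' @param q_cutoff FDR cutoff for the call.
#' @param pi0_method Passed to [storey_qvalues()].
#' @return A `switch_calls` window table with columns `distance`, `p`, `q`,
#'   `dRT`, `direction`; attributes `null` (the null distribution), `pi0`
#'   and `counts`.
#' @export
switch_test <- function(pm, layout, window_bp = 200000L, conditions = NULL,
                        q_cutoff = 0.01, pi0_method = "smoother",
                        scale_to_contrast = TRUE, recenter = TRUE) {
  wt <- average_windows(pm, layout, window_bp, conditions)
  wd <- .window_distances(pm, layout, window_bp, conditions, recenter)
  null <- build_null(pm, layout, window_bp, conditions,
                     scale_to_contrast = scale_to_contrast,
                     recenter = recenter)
  p <- empirical_pvalues(wd$distance, null)
  q <- storey_qvalues(p, pi0_method = pi0_method)
  wt$distance <- wd$distance
  wt$p <- p
  calls <- call_switches(wt, as.numeric(q), q_cutoff)
  attr(calls, "null") <- null
  attr(calls, "pi0") <- attr(q, "pi0")
  attr(calls, "window_bp") <- window_bp
  attr(calls, "conditions") <- attr(wt, "conditions")
  class(calls) <- c("switch_calls", class(calls))
  calls
}
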