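#' Median-center each sample's log2 ratios
#'
#' Per-sample normalization: the median of the non-missing values is
#' subtracted from every probe, aligning the genome-wide centres of all
#' arrays. Probe order is unchanged.
#'
#' @param pm A [probe_matrix()].
#' @return The probe matrix with centred values.
#' @export
normalize_arrays <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  for (j in seq_len(ncol(pm$values))) {
    v <- pm$values[, j]
    if (all(is.na(v))) {
      stop("sample '", colnames(pm$values)[j], "' has no non-missing values")
    }
    pm$values[, j] <- v - stats::median(v, na.rm = TRUE)
  }
  pm
}

#' Align conditions by their median probe-level contrast
#'
#' Per-sample median centering cannot remove a residual global offset
#' between conditions when part of the genome genuinely switches: the
#' switching mass drags the affected condition's own genome-wide median.
#' This step subtracts, from every sample of each non-reference condition,
#' the median of the probe-level difference between that condition's mean
#' profile and the reference condition's mean profile. The median of
#' differences is robust to switching as long as most of the genome is
#' unchanged, and a condition-wide shift leaves all within-condition
#' replicate differences untouched.
#'
#' @param pm A [probe_matrix()] (typically after [normalize_arrays()]).
#' @param conditions Optional ordered condition labels; the first is the
#'   reference. Defaults to sample-sheet order.
#' @return The probe matrix with aligned conditions.
#' @export
align_conditions <- function(pm, conditions = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (is.null(conditions)) conditions <- unique(pm$samples$condition)
  ref_cols <- which(pm$samples$condition == conditions[1])
  if (length(ref_cols) == 0L) stop("reference condition not found")
  ref <- rowMeans(pm$values[, ref_cols, drop = FALSE])
  for (cond in conditions[-1]) {
    cc <- which(pm$samples$condition == cond)
    if (length(cc) == 0L) stop("condition '", cond, "' not found")
    shift <- stats::median(rowMeans(pm$values[, cc, drop = FALSE]) - ref,
                           na.rm = TRUE)
    pm$values[, cc] <- pm$values[, cc] - shift
  }
  pm
}

.tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[abs(u) > 1] <- 0
  w
}

# Local linear tricube fit at every probe of one track. half = half-bandwidth
# in bp. Probes further than half away get zero weight. Falls back to the
# weighted mean when the local design is degenerate (fewer than 2 distinct
# usable positions).
.smooth_track_generic <- function(pos, y, half, idx = seq_along(y)) {
  ok <- !is.na(y)
  out <- rep(NA_real_, length(idx))
  for (m in seq_along(idx)) {
    i <- idx[m]
    sel <- which(ok & abs(pos - pos[i]) <= half)
    if (length(sel) == 0L) next
    x <- pos[sel] - pos[i]
    w <- .tricube(x / half)
    if (sum(w > 0) == 0L) { w <- rep(1, length(sel)) }
    s0 <- sum(w); s1 <- sum(w * x); s2 <- sum(w * x^2)
    t0 <- sum(w * y[sel]); t1 <- sum(w * x * y[sel])
    det <- s0 * s2 - s1^2
    if (length(sel) < 2L || det <= .Machine$double.eps * s0 * s2 + 1e-300) {
      out[m] <- t0 / s0
    } else {
      out[m] <- (s2 * t0 - s1 * t1) / det
    }
  }
  out
}

# Fast path for a complete track on a uniform grid: at interior probes the
# symmetric tricube weights cancel the slope term, so the local linear fit
# reduces to a fixed-kernel moving average (a convolution).
.smooth_track <- function(pos, y, half) {
  n <- length(y)
  if (n == 1L) return(y)
  d <- diff(pos)
  uniform <- !anyNA(y) && (max(d) - min(d)) < 1e-9
  if (!uniform) return(.smooth_track_generic(pos, y, half))
  k <- floor(half / d[1])
  if (k < 1L || n < 2L * k + 2L) return(.smooth_track_generic(pos, y, half))
  w <- .tricube((-k:k) * d[1] / half)
  out <- as.numeric(stats::filter(y, w / sum(w), sides = 2))
  edge <- c(seq_len(k), seq.int(n - k + 1L, n))
  out[edge] <- .smooth_track_generic(pos, y, half, idx = edge)
  out
}

#' Loess-smooth probe tracks along chromosomes
#'
#' Per chromosome and sample, each probe's smoothed value is a
#' tricube-weighted local linear regression over the probes within
#' `bandwidth_bp / 2` of its position. The bandwidth is fixed in bp (not a
#' span fraction) so smoothing behaves uniformly across chromosomes of
#' different probe density. Missing values are excluded from fits; where a
#' neighbourhood has fewer than two usable probes the weighted mean of what
#' is available is used instead.
#'
#' @param pm A [probe_matrix()].
#' @param bandwidth_bp Full smoothing window in bp (default 300 kb, i.e.
#'   +/- 150 kb around each probe).
#' @return The probe matrix with smoothed values, aligned to input probes.
#' @export
loess_smooth <- function(pm, bandwidth_bp = 300000) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (!is.finite(bandwidth_bp) || bandwidth_bp <= 0) {
    stop("bandwidth_bp must be positive")
  }
  half <- bandwidth_bp / 2
  for (cc in unique(pm$chrom)) {
    sel <- pm$chrom == cc
    if (sum(sel) < 2L) next
    p <- pm$pos[sel]
    for (j in seq_len(ncol(pm$values))) {
      pm$values[sel, j] <- .smooth_track(p, pm$values[sel, j], half)
    }
  }
  pm
}

#' Average probe signal into fixed windows
#'
#' Assigns each probe to the fixed-position tile containing it (0-based,
#' half-open: a probe at exactly a tile boundary belongs to the following
#' tile), averages per sample over non-missing probes, averages replicate
#' window means into condition means, and computes the replication-timing
#' differential dRT (second condition minus first). Windows without probes
#' carry `NA` and are excluded from downstream testing.
#'
#' @param pm A [probe_matrix()].
#' @param layout A [make_genome_layout()]; probes must lie within it.
#' @param window_bp Window width in bp (default 200 kb).
#' @param conditions Optional length-2 character giving (reference,
#'   alternative) condition labels; defaults to sample-sheet order.
#' @return A `window_table` data frame: `chrom`, `start`, `end`, `tile`,
#'   `n_probes`, one mean column per sample, `mean_<condition>` per
#'   condition, and `dRT`.
#' @export
average_windows <- function(pm, layout, window_bp = 200000L,
                            conditions = NULL) {
  stopifnot(inherits(pm, "probe_matrix"), inherits(layout, "genome_layout"))
  chrlen <- layout$length[match(pm$chrom, layout$chrom)]
  if (anyNA(chrlen)) {
    bad <- which(is.na(chrlen))[1]
    stop("probe on unknown chromosome: ", pm$chrom[bad])
  }
  beyond <- pm$pos < 0 | pm$pos >= chrlen
  if (any(beyond)) {
    bad <- which(beyond)[1]
    stop(sprintf("probe outside chromosome bounds: %s:%.0f",
                 pm$chrom[bad], pm$pos[bad]))
  }
  tiles <- genome_tiles(layout, window_bp)
  idx <- .tile_index(pm$chrom, pm$pos, layout, window_bp)

  vals <- pm$values
  nonmiss <- !is.na(vals)
  vals[!nonmiss] <- 0
  sums <- rowsum(vals, idx)
  cnts <- rowsum(nonmiss + 0, idx)
  means <- sums / cnts
  means[cnts == 0] <- NA_real_

  wt <- tiles
  wt$n_probes <- tabulate(idx, nbins = nrow(tiles))
  rows <- as.integer(rownames(sums))
  smat <- matrix(NA_real_, nrow(tiles), ncol(vals),
                 dimnames = list(NULL, colnames(pm$values)))
  smat[rows, ] <- means
  wt <- cbind(wt, as.data.frame(smat))

  cols <- .condition_columns(pm, conditions)
  for (cond in names(cols)) {
    wt[[paste0("mean_", cond)]] <- rowMeans(smat[, cols[[cond]], drop = FALSE])
  }
  wt$dRT <- wt[[paste0("mean_", names(cols)[2])]] -
    wt[[paste0("mean_", names(cols)[1])]]
  attr(wt, "window_bp") <- window_bp
  attr(wt, "conditions") <- names(cols)
  attr(wt, "samples") <- pm$samples
  class(wt) <- c("window_table", "data.frame")
  wt
}
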