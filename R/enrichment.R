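#' Count binding sites per fixed window
#'
#' Interval sites are reduced to their midpoints (peak summits approximate
#' points at 200-Kb resolution); counting is half-open, so a site at exactly
#' a tile boundary belongs to the following tile.
#'
#' @param sites Data frame with `chrom` and either `pos` (points) or
#'   `start`/`end` (intervals).
#' @param layout Genome layout.
#' @param window_bp Tile width in bp.
#' @return Integer vector of counts aligned to [genome_tiles()].
#' @export
count_sites_per_window <- function(sites, layout, window_bp = 200000L) {
  stopifnot(inherits(layout, "genome_layout"))
  tiles <- genome_tiles(layout, window_bp)
  if (nrow(sites) == 0L) return(integer(nrow(tiles)))
  pos <- if ("pos" %in% names(sites)) sites$pos else
    floor((sites$start + sites$end) / 2)
  chrlen <- layout$length[match(sites$chrom, layout$chrom)]
  bad <- is.na(chrlen) | pos < 0 | pos >= chrlen
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("site outside chromosome bounds: %s:%.0f",
                 sites$chrom[i], pos[i]))
  }
  idx <- .tile_index(sites$chrom, pos, layout, window_bp)
  tabulate(idx, nbins = nrow(tiles))
}

#' Smoothed site density as a function of replication timing
#'
#' Local tricube-weighted mean of window site counts along the window RT
#' axis, evaluated on a regular grid, with a per-point standard error from
#' the local weighted variance (the site-density-versus-timing curve with
#' its error band).
#'
#' @param counts Site counts per window.
#' @param rt Window RT values aligned with `counts` (`NA` dropped).
#' @param bandwidth Smoothing half-width on the RT axis (log2 units).
#' @param n_grid Number of evaluation points.
#' @return Data frame: `rt`, `mean`, `se`, `n_eff` (local effective count).
#' @export
enrichment_curve <- function(counts, rt, bandwidth = 0.5, n_grid = 50L) {
  ok <- !is.na(rt) & !is.na(counts)
  x <- rt[ok]; y <- counts[ok]
  if (length(x) == 0L) stop("no usable windows")
  if (diff(range(x)) == 0) {
    message("degenerate RT range; returning a single-point curve")
    grid <- x[1]
  } else {
    grid <- seq(min(x), max(x), length.out = n_grid)
  }
  out <- lapply(grid, function(g) {
    w <- .tricube((x - g) / bandwidth)
    if (sum(w > 0) == 0L) return(c(NA_real_, NA_real_, 0))
    mu <- sum(w * y) / sum(w)
    v <- sum(w * (y - mu)^2) / sum(w)
    n_eff <- sum(w)^2 / sum(w^2)
    c(mu, sqrt(v / n_eff), n_eff)
  })
  out <- do.call(rbind, out)
  data.frame(rt = grid, mean = out[, 1], se = out[, 2], n_eff = out[, 3])
}

#' Mean site counts by switch class
#'
#' Arithmetic mean of window site counts for EtoL, LtoE and non-switching
#' windows, plus the projection of the per-window mean onto a domain size
#' range (`mean_per_window * size / window_bp`), giving the expected number
#' of sites per switching domain.
#'
#' @param counts Site counts aligned to the call table's windows.
#' @param calls A [call_switches()] / [switch_test()] table (needs
#'   `direction`).
#' @param domain_size_bp Length-2 domain size range for the projection.
#' @param window_bp Window width in bp.
#' @return Data frame with one row per class (`EtoL`, `LtoE`, `none`):
#'   `n_windows`, `mean_sites`, `projected_low`, `projected_high` (the
#'   projection for switching classes, `NA` means an empty class).
#' @export
class_mean_sites <- function(counts, calls, domain_size_bp = c(4e5, 8e5),
                             window_bp = 200000L) {
  stopifnot(length(counts) == nrow(calls), "direction" %in% names(calls))
  classes <- c("EtoL", "LtoE", "none")
  rows <- lapply(classes, function(cl) {
    i <- which(calls$direction == cl)
    m <- if (length(i) > 0) mean(counts[i]) else NA_real_
    data.frame(class = cl, n_windows = length(i), mean_sites = m,
               projected_low = m * domain_size_bp[1] / window_bp,
               projected_high = m * domain_size_bp[2] / window_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exact two-sided rank-sum p-value by full enumeration of the C(n, n1)
# group assignments on the (tie-averaged) ranks. Inclusive both tails,
# doubled and capped at 1.
.wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  assignments <- utils::combn(n, n1)
  ws <- colSums(matrix(rk[assignments], nrow = n1))
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

#' Wilcoxon rank-sum test for a replication-timing shift
#'
#' Two-sided rank-sum p-value comparing the timing values of affected
#' windows between two states. Small samples (`n1 + n2 <= 12`) use exact
#' enumeration over all group assignments (ties handled by midranks); larger
#' samples use the normal approximation with tie correction.
#'
#' @param rt_control,rt_mutant Numeric samples (non-empty).
#' @return Two-sided p-value.
#' @export
wilcoxon_rt_shift <- function(rt_control, rt_mutant) {
  x <- rt_control[!is.na(rt_control)]
  y <- rt_mutant[!is.na(rt_mutant)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    message("all values tied across both samples; p = 1")
    return(1)
  }
  if (length(x) + length(y) <= 12L) {
    .wilcoxon_exact(x, y)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE)$p.value)
  }
}

#' Association between expression change and timing switching
#'
#' Relates per-gene log2 fold-changes to the switch status of the windows
#' holding the genes: the overall Pearson R between window dRT and gene
#' log2 fold-change over genes in switching windows, the number of
#' target-flagged genes in switching windows changing more than the
#' fold-change threshold (strict inequality), and per-class fold-change
#' summaries for box-plot style export. Non-switching windows are split at
#' RT 0 into EtoE (early in both conditions) and LtoL (late in both).
#'
#' @param expr An [simulate_expression()]-style table (`tile`, `log2fc`,
#'   `is_target`).
#' @param calls A [switch_test()] call table aligned to the tile frame.
#' @param fc_threshold_log2 Exceedance threshold on |log2FC| (default 1,
#'   i.e. two-fold; equality is not an exceedance).
#' @return List: `overall_r`, `n_genes_switching`, `target_exceedance`
#'   (count), `n_targets_switching`, `class_summary` (data frame).
#' @export
expression_vs_switch <- function(expr, calls, fc_threshold_log2 = 1.0) {
  stopifnot(all(c("tile", "log2fc", "is_target") %in% names(expr)),
            all(c("direction", "dRT") %in% names(calls)))
  conds <- attr(calls, "conditions")
  mean_a <- calls[[paste0("mean_", conds[1])]]
  mean_b <- calls[[paste0("mean_", conds[2])]]
  wclass <- rep(NA_character_, nrow(calls))
  wclass[calls$direction == "EtoL"] <- "EtoL"
  wclass[calls$direction == "LtoE"] <- "LtoE"
  non <- calls$direction == "none"
  wclass[non & mean_a > 0 & mean_b > 0] <- "EtoE"
  wclass[non & mean_a < 0 & mean_b < 0] <- "LtoL"

  gcls <- wclass[expr$tile]
  gdrt <- calls$dRT[expr$tile]
  switching <- gcls %in% c("EtoL", "LtoE")
  overall_r <- NA_real_
  if (sum(switching) >= 3 && stats::sd(gdrt[switching]) > 0 &&
      stats::sd(expr$log2fc[switching]) > 0) {
    overall_r <- stats::cor(gdrt[switching], expr$log2fc[switching])
  } else {
    message("overall R not estimable over switching windows")
  }
  exceed <- sum(expr$is_target & switching &
                  abs(expr$log2fc) > fc_threshold_log2)
  summ <- lapply(c("EtoL", "LtoE", "EtoE", "LtoL"), function(cl) {
    v <- expr$log2fc[!is.na(gcls) & gcls == cl]
    data.frame(class = cl, n_genes = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(overall_r = overall_r,
       n_genes_switching = sum(switching),
       target_exceedance = exceed,
       n_targets_switching = sum(expr$is_target & switching),
       class_summary = do.call(rbind, summ))
}
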