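# Exhaustive single-changepoint scan: for every split k in
# [min_width, n - min_width], the two-sample pooled-variance t statistic
# between y[1:k] and y[(k+1):n]. Returns the argmax of |t| and the value.
# Degenerate pooled variance: equal means give t = 0, different means Inf.
.max_t_scan <- function(y, min_width) {
  n <- length(y)
  ks <- seq.int(min_width, n - min_width)
  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  nl <- ks
  nr <- n - ks
  ml <- cs[ks] / nl
  mr <- (cs[n] - cs[ks]) / nr
  ssl <- cs2[ks] - nl * ml^2
  ssr <- (cs2[n] - cs2[ks]) - nr * mr^2
  sp2 <- pmax(ssl + ssr, 0) / (n - 2)
  se <- sqrt(sp2 * (1 / nl + 1 / nr))
  t <- ifelse(se > 0, abs(ml - mr) / se,
              ifelse(abs(ml - mr) > 0, Inf, 0))
  best <- which.max(t)
  list(k = ks[best], t = t[best])
}

#' Best single changepoint of a segment
#'
#' Exhaustive scan over all admissible split positions of one ordered value
#' vector, returning the split maximizing the absolute two-sample
#' pooled-variance t statistic between the left and right parts. This is
#' the elementary move of [cbs_segment()]; exposed for inspection and
#' verification.
#'
#' @param y Ordered numeric values (no missing).
#' @param min_width Minimum probes on each side of the split.
#' @return List: `k` (last index of the left part), `t` (the max |t|;
#'   `Inf` for a noiseless mean change, 0 for constant input).
#' @export
best_split <- function(y, min_width = 5L) {
  if (length(y) < 2L * min_width) stop("too few values for a split")
  if (anyNA(y)) stop("missing values not allowed")
  .max_t_scan(y, min_width)
}

# Permutation p-value for the best split of one segment, with early
# termination once the decision "p > alpha" is certain.
.split_pvalue <- function(y, min_width, n_perm, alpha) {
  obs <- .max_t_scan(y, min_width)
  if (obs$t == 0) return(list(k = obs$k, p = 1))
  limit <- alpha * (1 + n_perm) - 1  # max exceedances compatible with accept
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    tb <- .max_t_scan(sample(y), min_width)$t
    if (tb >= obs$t) {
      cnt <- cnt + 1L
      if (cnt > limit) return(list(k = obs$k, p = (1 + cnt) / (1 + b),
                                   early = TRUE))
    }
  }
  list(k = obs$k, p = (1 + cnt) / (1 + n_perm))
}

.segment_recurse <- function(y, offset, alpha, min_width, n_perm) {
  n <- length(y)
  if (n < 2L * min_width) return(offset + c(0L, n))
  sp <- .split_pvalue(y, min_width, n_perm, alpha)
  if (sp$p > alpha) return(offset + c(0L, n))
  left <- .segment_recurse(y[seq_len(sp$k)], offset, alpha, min_width, n_perm)
  right <- .segment_recurse(y[seq.int(sp$k + 1L, n)], offset + sp$k,
                            alpha, min_width, n_perm)
  sort(unique(c(left, right)))
}

#' Segment a per-probe differential profile into domains
#'
#' Recursive binary segmentation of an ordered per-probe dRT track into
#' contiguous constant-mean domains, in the spirit of circular binary
#' segmentation: for each candidate segment the single changepoint
#' maximizing the two-sample t statistic is found by exhaustive scan, the
#' split is accepted when its within-segment permutation p-value (seeded,
#' `n_perm` shuffles) is at most `alpha` and both children have at least
#' `min_width` probes, and recursion continues until no split is accepted.
#' Adjacent segments whose means differ by less than `merge_tol` are merged.
#'
#' Missing values are dropped (their positions retained for boundary
#' placement via the neighbouring probes). A chromosome with fewer than
#' `2 * min_width` usable probes yields a single segment with a message.
#'
#' @param chrom Chromosome of each probe (single value recycled).
#' @param pos Probe positions in bp, increasing within chromosome.
#' @param drt Per-probe dRT values (typically normalized, unsmoothed).
#' @param alpha Permutation significance level for accepting a split.
#' @param min_width Minimum probes per segment.
#' @param n_perm Permutations per tested split.
#' @param merge_tol Merge adjacent segments closer than this in mean.
#' @param seed Optional integer seed for the permutations.
#' @return A `domain_segments` data frame: `chrom`, `first_pos`, `last_pos`
#'   (first/last probe position), `gap_prev`/`gap_next` (bp to the adjacent
#'   probe beyond the segment, `NA` at chromosome ends), `n_probes`,
#'   `mean_dRT`. Class assignment is left to [classify_segments()].
#' @export
cbs_segment <- function(chrom, pos, drt, alpha = 0.01, min_width = 5L,
                        n_perm = 1000L, merge_tol = 0.1, seed = NULL) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(pos) == length(drt), length(chrom) == length(pos))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  for (cc in unique(chrom)) {
    sel <- chrom == cc & !is.na(drt)
    y <- drt[sel]
    p <- pos[sel]
    n <- length(y)
    if (n == 0L) next
    if (n < 2L * min_width) {
      message("chromosome ", cc, ": too few probes (", n,
              "), returning a single segment")
      bounds <- c(0L, n)
    } else {
      bounds <- .segment_recurse(y, 0L, alpha, min_width, n_perm)
    }
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1L]
    means <- vapply(seq_along(starts), function(i) {
      mean(y[starts[i]:ends[i]])
    }, 0)
    # merge adjacent segments with nearly equal means
    keep_going <- TRUE
    while (keep_going && length(starts) > 1L) {
      dmean <- abs(diff(means))
      j <- which(dmean < merge_tol)
      if (length(j) == 0L) { keep_going <- FALSE; break }
      j <- j[1]
      starts <- starts[-(j + 1L)]
      new_end <- ends[j + 1L]
      ends <- ends[-j]
      ends[j] <- new_end
      means <- vapply(seq_along(starts), function(i) {
        mean(y[starts[i]:ends[i]])
      }, 0)
    }
    gap_prev <- c(NA_real_, p[starts[-1L]] - p[ends[-length(ends)]])
    gap_next <- c(p[starts[-1L]] - p[ends[-length(ends)]], NA_real_)
    out[[cc]] <- data.frame(chrom = cc,
                            first_pos = p[starts], last_pos = p[ends],
                            gap_prev = gap_prev, gap_next = gap_next,
                            n_probes = ends - starts + 1L,
                            mean_dRT = means, stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  class(segs) <- c("domain_segments", "data.frame")
  segs
}

#' Classify segments as EtoL / LtoE / none and assign bp extents
#'
#' A segment is EtoL when its mean dRT is at or below `-class_threshold`,
#' LtoE at or above `+class_threshold`, otherwise non-switching. Segment bp
#' boundaries follow the midpoint rule: the boundary between two adjacent
#' segments is halfway between the last probe of one and the first probe of
#' the next; terminal boundaries are clamped to the chromosome ends when a
#' layout is supplied (otherwise to the outermost probes).
#'
#' @param segments Output of [cbs_segment()].
#' @param class_threshold Absolute mean-dRT threshold (log2 units) for
#'   calling a segment switching.
#' @param layout Optional [make_genome_layout()] for end clamping.
#' @return The segments with `start`, `end`, `size` (bp) and `class`
#'   columns.
#' @export
classify_segments <- function(segments, class_threshold = 0.5,
                              layout = NULL) {
  stopifnot(inherits(segments, "domain_segments") || is.data.frame(segments))
  s <- segments
  start <- ifelse(is.na(s$gap_prev), NA_real_, s$first_pos - s$gap_prev / 2)
  end <- ifelse(is.na(s$gap_next), NA_real_, s$last_pos + s$gap_next / 2)
  for (cc in unique(s$chrom)) {
    i <- which(s$chrom == cc)
    chrom_end <- if (!is.null(layout)) {
      layout$length[match(cc, layout$chrom)]
    } else s$last_pos[i[length(i)]]
    start[i[1]] <- 0
    end[i[length(i)]] <- chrom_end
  }
  s$start <- pmax(start, 0)
  s$end <- end
  s$size <- s$end - s$start
  s$class <- "none"
  s$class[s$mean_dRT <= -class_threshold] <- "EtoL"
  s$class[s$mean_dRT >= class_threshold] <- "LtoE"
  s
}
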