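#' Pearson correlation matrix of windowed timing profiles
#'
#' Pairwise-complete Pearson correlation across a set of windowed RT
#' vectors sharing one tile frame (the dataset-by-dataset correlation
#' heatmap view). Entries with fewer than 3 pairwise-complete windows, or a
#' zero-variance member, are `NA` (with a message).
#'
#' @param profiles Named list of aligned numeric vectors, or a matrix with
#'   one column per dataset.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(profiles) {
  x <- if (is.list(profiles)) {
    stopifnot(length(unique(lengths(profiles))) == 1L)
    do.call(cbind, profiles)
  } else as.matrix(profiles)
  if (is.null(colnames(x))) colnames(x) <- paste0("dataset", seq_len(ncol(x)))
  k <- ncol(x)
  r <- diag(1, k)
  dimnames(r) <- list(colnames(x), colnames(x))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      ok <- stats::complete.cases(x[, c(i, j)])
      if (sum(ok) < 3L) {
        message("fewer than 3 pairwise-complete windows for ",
                colnames(x)[i], " vs ", colnames(x)[j])
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      a <- x[ok, i]; b <- x[ok, j]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        message("zero variance in ", colnames(x)[i], " or ", colnames(x)[j])
        r[i, j] <- r[j, i] <- NA_real_
      } else {
        r[i, j] <- r[j, i] <- stats::cor(a, b)
      }
    }
  }
  r
}

#' Correlation of two aligned dRT vectors
#'
#' @param drt_a,drt_b Aligned windowed dRT vectors.
#' @return Pearson R (scalar, `NA` on degenerate input).
#' @export
drt_correlation <- function(drt_a, drt_b) {
  pearson_matrix(list(a = drt_a, b = drt_b))[1, 2]
}

#' Overlap counts between two window-id sets
#'
#' @param set_a,set_b Vectors of window/tile identifiers on one tile frame.
#' @return Named vector `c(only_a, both, only_b)`.
#' @export
overlap_counts <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- length(intersect(a, b))
  c(only_a = length(a) - both, both = both, only_b = length(b) - both)
}

#' Permutation test for window-set overlap
#'
#' Tests whether the overlap between two window sets exceeds what uniform
#' random placement would give: `set_b` is re-drawn uniformly without
#' replacement over the tile frame `n_perm` times and the right-tail
#' add-one p-value of the observed intersection size is reported.
#'
#' @param set_a,set_b Window-id vectors (non-empty).
#' @param frame All tile ids of the frame, or a single integer tile count
#'   (ids then being `1:frame`).
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return List: `p`, `observed`, `perm_mean`, `n_perm`.
#' @export
overlap_permutation_test <- function(set_a, set_b, frame, n_perm = 999L,
                                     seed = NULL) {
  ids <- if (length(frame) == 1L && is.numeric(frame)) seq_len(frame) else
    unique(frame)
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) < 1L || length(b) < 1L) stop("both sets must be non-empty")
  if (length(b) > length(ids)) stop("set_b exceeds the tile frame")
  if (!all(a %in% ids) || !all(b %in% ids)) {
    stop("sets contain ids outside the tile frame")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  in_a <- ids %in% a
  observed <- length(intersect(a, b))
  perm <- vapply(seq_len(n_perm), function(i) {
    sum(in_a[sample.int(length(ids), length(b))])
  }, 0L)
  list(p = (1 + sum(perm >= observed)) / (1 + n_perm),
       observed = observed, perm_mean = mean(perm), n_perm = n_perm)
}

#' Align switching domains to a reference panel of cell-type profiles
#'
#' For each affected domain, the window-level distance/p/q machinery is run
#' comparing the target's windowed RT to each reference profile; a domain is
#' "aligned" to a reference when none of its windows is significantly
#' different at `q <= q_cutoff_ref`, and aligned overall when this holds for
#' at least one reference. The window-level empirical null is built from the
#' target's within-group replicate window means (pair differences scaled by
#' `sqrt(1/(2 * n))`, treating the reference as noise-free).
#'
#' @param wt A window table from [average_windows()] on the target dataset.
#' @param domains Data frame of affected domains (`chrom`, `start`, `end`),
#'   e.g. classified switching segments.
#' @param panel Matrix (tiles x references, named columns) of reference
#'   windowed RT aligned to `wt`'s tile frame.
#' @param target_condition Condition whose mean windowed RT is compared;
#'   defaults to the second (alternative) condition.
#' @param q_cutoff_ref q-value cutoff below which a window counts as
#'   significantly different from a reference.
#' @return List: `domains` (input plus logical `aligned`), `aligned_fraction`,
#'   and the per-domain-by-reference logical matrix `aligned_by_ref`.
#' @export
developmental_alignment <- function(wt, domains, panel,
                                    target_condition = NULL,
                                    q_cutoff_ref = 0.2) {
  stopifnot(inherits(wt, "window_table"))
  panel <- as.matrix(panel)
  if (ncol(panel) < 1L) stop("empty reference panel")
  if (nrow(panel) != nrow(wt)) stop("panel not aligned to the tile frame")
  conds <- attr(wt, "conditions")
  if (is.null(target_condition)) target_condition <- conds[2]
  target <- wt[[paste0("mean_", target_condition)]]

  samples <- attr(wt, "samples")
  reps <- samples$sample[samples$condition == target_condition]
  if (length(reps) < 2L) stop("target condition needs >= 2 replicates")
  pool <- numeric(0)
  prs <- utils::combn(reps, 2L)
  scale <- sqrt(1 / (2 * length(reps)))
  for (k in seq_len(ncol(prs))) {
    d <- abs(wt[[prs[1, k]]] - wt[[prs[2, k]]]) * scale
    pool <- c(pool, d[!is.na(d)])
  }
  if (length(pool) == 0L) stop("no usable windows for the null")

  dom_windows <- lapply(seq_len(nrow(domains)), function(i) {
    which(wt$chrom == domains$chrom[i] & wt$start < domains$end[i] &
            wt$end > domains$start[i] & !is.na(target))
  })
  aligned_by_ref <- matrix(NA, nrow(domains), ncol(panel),
                           dimnames = list(NULL, colnames(panel)))
  for (r in seq_len(ncol(panel))) {
    d <- abs(target - panel[, r])
    p <- empirical_pvalues(d, pool)
    q <- storey_qvalues(p, pi0_method = "fixed_1")
    for (i in seq_along(dom_windows)) {
      w <- dom_windows[[i]]
      aligned_by_ref[i, r] <- length(w) > 0 && all(q[w] > q_cutoff_ref)
    }
  }
  domains$aligned <- apply(aligned_by_ref, 1, any)
  list(domains = domains,
       aligned_fraction = mean(domains$aligned),
       aligned_by_ref = aligned_by_ref)
}
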