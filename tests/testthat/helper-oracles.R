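# Independent oracle implementations used to cross-check the package. These
# deliberately use different algorithms / code paths from the implementation.

# Brute-force Benjamini-Hochberg: literal step-up definition with an
# explicit double loop (no cummin trick).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) m * p[o][j] / j, 0), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive single-changepoint max-t scan via t.test() calls.
brute_max_t <- function(y, min_width) {
  n <- length(y)
  ks <- seq.int(min_width, n - min_width)
  ts <- vapply(ks, function(k) {
    a <- y[1:k]; b <- y[(k + 1):n]
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      if (mean(a) == mean(b)) 0 else Inf
    } else {
      abs(unname(stats::t.test(a, b, var.equal = TRUE)$statistic))
    }
  }, 0)
  list(k = ks[which.max(ts)], t = max(ts))
}

# Exact two-sided rank-sum p by bitmask enumeration over group labellings.
brute_wilcox <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) == n1) ws <- c(ws, sum(rk[sel]))
  }
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Tricube-weighted local linear fit at a single position, via lm.wfit.
tricube_wls_fit <- function(pos, y, x0, half) {
  sel <- which(abs(pos - x0) <= half & !is.na(y))
  x <- pos[sel] - x0
  w <- (1 - pmin(abs(x / half), 1)^3)^3
  fit <- stats::lm.wfit(cbind(1, x), y[sel], w)
  unname(fit$coefficients[1])
}
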