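sheet22 <- two_by_two_sheet()

test_that("segment distance matches hand computations", {
  # group means (0,0) vs (3,4) over two probes: sqrt(25/2)
  v <- cbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  colnames(v) <- sheet22$sample
  expect_equal(segment_distance(v, sheet22), sqrt(25 / 2))
  # identical group means
  v2 <- cbind(c(1, 2), c(3, 0), c(2, 1), c(2, 1))
  colnames(v2) <- sheet22$sample
  expect_equal(segment_distance(v2, sheet22), 0)
  # single probe reduces to the absolute difference
  v3 <- matrix(c(1.2, 1.2, 0.2, 0.2), 1, 4,
               dimnames = list(NULL, sheet22$sample))
  expect_equal(segment_distance(v3, sheet22), 1.0)
})

test_that("segment distance is invariant to group exchange and shifts", {
  set.seed(4)
  for (rep in 1:5) {
    v <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, sheet22$sample))
    d <- segment_distance(v, sheet22)
    swapped <- sheet22
    swapped$condition <- rev(sheet22$condition)
    expect_equal(segment_distance(v, swapped), d)
    expect_equal(segment_distance(v + 3.7, sheet22), d)
  }
})

test_that("the empirical null pools scaled within-group pair distances", {
  layout <- tiny_layout(c(chr1 = 6e5))
  # one testable window; group A replicates (0,0) and (3,4)
  v <- cbind(c(0, 0), c(3, 4), c(1, 1), c(1, 1))
  colnames(v) <- sheet22$sample
  pm <- probe_matrix(rep("chr1", 2), c(1e4, 5e4), v, sheet22)
  raw <- build_null(pm, layout, scale_to_contrast = FALSE, recenter = FALSE)
  # one pair per group for the single testable window
  expect_equal(raw$n, 2L)
  expect_equal(sort(raw$distances), c(0, sqrt(25 / 2)))
  scaled <- build_null(pm, layout, recenter = FALSE)
  expect_equal(sort(scaled$distances), c(0, sqrt(25 / 2)) * sqrt(1 / 2))

  # 2 groups x 2 replicates over W testable windows: null size 2 W
  layout2 <- tiny_layout(c(chr1 = 2e6))
  set.seed(9)
  pm2 <- make_pm(matrix(rnorm(364 * 4), 364, 4))  # probes reach every tile
  null2 <- build_null(pm2, layout2)
  expect_equal(null2$n, 2L * 10L)

  # noiseless identical replicates: all-zero null
  pm3 <- make_pm(matrix(rep(rnorm(364), 4), ncol = 4))
  expect_equal(unique(build_null(pm3, layout2)$distances), 0)

  one_rep <- data.frame(sample = c("a", "b", "c"),
                        condition = c("x", "x", "y"), replicate = c(1, 2, 1))
  pm4 <- probe_matrix(rep("chr1", 2), c(0, 5500), matrix(1, 2, 3,
                      dimnames = list(NULL, one_rep$sample)), one_rep)
  expect_error(build_null(pm4, layout), "replicates")
})

test_that("empirical p-values count the null right tail inclusively", {
  null <- c(1, 2, 3)
  expect_equal(empirical_pvalues(2.5, null), 0.5)
  expect_equal(empirical_pvalues(0, null), 1.0)
  expect_equal(empirical_pvalues(10, null), 0.25)
  # ties counted with >= : d equal to a null value includes it
  expect_equal(empirical_pvalues(2, null), (1 + 2) / 4)
  # monotone non-increasing in d, always in (0, 1]
  set.seed(2)
  big_null <- rexp(500)
  d <- sort(runif(100, 0, 4))
  p <- empirical_pvalues(d, big_null)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(empirical_pvalues(1, numeric(0)), "empty")
})

test_that("q-values with pi0 fixed at 1 equal Benjamini-Hochberg exactly", {
  q <- storey_qvalues(c(0.01, 0.02, 0.9), pi0_method = "fixed_1")
  expect_equal(as.numeric(q), c(0.03, 0.03, 0.9))
  expect_equal(as.numeric(storey_qvalues(0.37, pi0_method = "fixed_1")), 0.37)

  set.seed(13)
  for (rep in 1:25) {
    p <- runif(sample(1:50, 1))
    q <- storey_qvalues(p, pi0_method = "fixed_1")
    expect_equal(as.numeric(q), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("the pi0 smoother is clamped and bounds the q-values", {
  p_all1 <- rep(1, 30)
  q <- storey_qvalues(p_all1)
  expect_true(all(q <= 1))
  expect_equal(as.numeric(q), rep(attr(q, "pi0"), 30))

  set.seed(3)
  p <- runif(2000)  # pure null: pi0 should be near 1, never outside (0, 1]
  q <- storey_qvalues(p)
  expect_true(attr(q, "pi0") > 0 && attr(q, "pi0") <= 1)

  expect_error(storey_qvalues(c(0.5, 0)), "0, 1")
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("switch calls follow the dRT sign convention", {
  w <- data.frame(chrom = "chr1", start = c(0, 2e5, 4e5, 6e5),
                  end = c(2e5, 4e5, 6e5, 8e5),
                  dRT = c(-0.8, 0.8, -0.8, 0))
  calls <- call_switches(w, c(0.005, 0.005, 0.2, 0.5), q_cutoff = 0.01)
  expect_equal(calls$direction, c("EtoL", "LtoE", "none", "none"))
  expect_equal(unname(attr(calls, "counts")[c("EtoL", "LtoE")]), c(1L, 1L))
  expect_error(call_switches(w, rep(0.5, 4), q_cutoff = 0), "0, 1")
  expect_error(call_switches(w, rep(0.5, 4), q_cutoff = 1), "0, 1")
  expect_warning(call_switches(w, c(0.5, 0.5, 0.5, 0.001), q_cutoff = 0.01),
                 "dRT exactly 0")
})

test_that("windowed distances agree with per-window segment_distance", {
  layout <- tiny_layout(c(chr1 = 2e6))
  set.seed(44)
  pm <- make_pm(matrix(rnorm(320 * 4), 320, 4))
  calls <- switch_test(pm, layout, recenter = FALSE)
  idx <- floor(pm$pos / 2e5) + 1
  for (w in c(1, 4, 10)) {
    expect_equal(calls$distance[w],
                 segment_distance(pm$values[idx == w, , drop = FALSE],
                                  sheet22))
  }
})

test_that("a noiseless no-switch dataset yields zero distances and no calls", {
  layout <- tiny_layout(c(chr1 = 4e6))
  pm <- make_pm(matrix(rep(rnorm(700), 4), ncol = 4))
  calls <- switch_test(pm, layout)
  testable <- !is.na(calls$distance)
  expect_true(all(calls$distance[testable] == 0))
  expect_equal(unname(attr(calls, "counts")[c("EtoL", "LtoE")]), c(0L, 0L))
})

test_that("strong injected switches are detected with correct direction", {
  # all-EtoL but with modest switched mass (~12% of the genome): the
  # empirical null assumes most of the genome is unchanged
  layout <- make_genome_layout(c(chr1 = 5e7))
  cfg <- sim_config(n_switch_domains = 12L, switch_size_bp = c(4e5, 6e5),
                    switch_effect_range = c(1.5, 1.5),
                    switch_direction_mix = 1, probe_noise_sd = 0.2,
                    seed = 17L)
  sim <- simulate_rt_dataset(layout, cfg)
  calls <- switch_test(normalize_arrays(sim$probes), layout)
  cnt <- attr(calls, "counts")
  expect_gte(unname(cnt["EtoL"]), 1L)
  ev <- evaluate_calls(calls, sim$truth, layout)
  expect_equal(ev$domain_sensitivity, 1)
  expect_lt(ev$fdp, 0.05)
})
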