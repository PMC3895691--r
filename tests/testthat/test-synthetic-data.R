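layout2 <- make_genome_layout(c(chr1 = 2e7, chr2 = 1e7))

test_that("simulation is bit-identical given the seed", {
  cfg <- sim_config(n_switch_domains = 5L, seed = 11L)
  a <- simulate_rt_dataset(layout2, cfg)
  b <- simulate_rt_dataset(layout2, cfg)
  expect_identical(a$probes$values, b$probes$values)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- simulate_rt_dataset(layout2, sim_config(n_switch_domains = 5L,
                                               seed = 12L))
  expect_false(identical(a$probes$values, c$probes$values))
})

test_that("noiseless null gives identical samples probe by probe", {
  cfg <- sim_config(probe_noise_sd = 0, replicate_offset_sd = 0,
                    n_switch_domains = 0L, seed = 3L)
  sim <- simulate_rt_dataset(layout2, cfg)
  v <- sim$probes$values
  for (j in 2:4) expect_equal(v[, j], v[, 1], ignore_attr = TRUE)
})

test_that("injected effects appear in condition B only, exactly", {
  cfg <- sim_config(probe_noise_sd = 0, replicate_offset_sd = 0,
                    n_switch_domains = 1L, switch_size_bp = c(6e5, 6e5),
                    switch_effect_range = c(1.5, 1.5),
                    switch_direction_mix = 1, seed = 21L)
  sim <- simulate_rt_dataset(layout2, cfg)
  tr <- sim$truth
  expect_equal(tr$direction, "EtoL")
  expect_equal(tr$effect, -1.5)
  pm <- sim$probes
  inside <- pm$chrom == tr$chrom & pm$pos >= tr$start & pm$pos < tr$end
  drt <- rowMeans(pm$values[, 3:4]) - rowMeans(pm$values[, 1:2])
  expect_equal(unique(drt[inside]), -1.5)
  expect_equal(unique(drt[!inside]), 0)
})

test_that("windowed dRT inside an injected domain recovers the effect", {
  cfg <- sim_config(probe_noise_sd = 0, replicate_offset_sd = 0,
                    n_switch_domains = 3L, switch_direction_mix = 1,
                    seed = 8L)
  sim <- simulate_rt_dataset(layout2, cfg)
  wt <- average_windows(sim$probes, layout2)
  for (i in seq_len(nrow(sim$truth))) {
    interior <- wt$chrom == sim$truth$chrom[i] &
      wt$start >= sim$truth$start[i] & wt$end <= sim$truth$end[i]
    if (any(interior)) {
      expect_equal(wt$dRT[interior],
                   rep(sim$truth$effect[i], sum(interior)),
                   tolerance = 1e-12)
    }
  }
})

test_that("injected domains are disjoint and within chromosome bounds", {
  for (s in 1:5) {
    cfg <- sim_config(n_switch_domains = 12L, seed = s)
    tr <- simulate_rt_dataset(layout2, cfg)$truth
    expect_equal(nrow(tr), 12L)
    for (cc in unique(tr$chrom)) {
      d <- tr[tr$chrom == cc, ]
      d <- d[order(d$start), ]
      len <- layout2$length[layout2$chrom == cc]
      expect_true(all(d$start >= 0 & d$end <= len))
      if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    }
    expect_true(all((tr$direction == "EtoL") == (tr$effect < 0)))
  }
})

test_that("a supplied truth is reused with fresh noise", {
  cfg <- sim_config(n_switch_domains = 6L, seed = 31L)
  a <- simulate_rt_dataset(layout2, cfg)
  cfg2 <- cfg; cfg2$seed <- 32L
  b <- simulate_rt_dataset(layout2, cfg2, truth = a$truth)
  expect_equal(as.data.frame(a$truth)[c("chrom", "start", "end", "effect")],
               as.data.frame(b$truth)[c("chrom", "start", "end", "effect")])
  expect_false(identical(a$probes$values, b$probes$values))
})

test_that("impossible domain placement raises a placement error", {
  small <- make_genome_layout(c(chr1 = 1e6))
  cfg <- sim_config(n_switch_domains = 5L, switch_size_bp = c(8e5, 8e5),
                    seed = 1L)
  expect_error(simulate_rt_dataset(small, cfg), "place")
})

test_that("binding-site counts follow the Poisson rate model", {
  n <- 10000
  tiles <- data.frame(chrom = "chr1",
                      start = seq(0, by = 2e5, length.out = n),
                      end = seq(2e5, by = 2e5, length.out = n),
                      tile = seq_len(n))
  big <- make_genome_layout(c(chr1 = n * 2e5))

  # b = 0, a = ln 2: mean count 2 within 3 standard errors of Poisson
  s <- simulate_binding_sites(tiles, rep(0, n), c(log(2), 0), seed = 5L)
  cnt <- count_sites_per_window(s, big)
  expect_lt(abs(mean(cnt) - 2), 3 * sqrt(2 / n))

  # zero rate: no sites at all
  s0 <- simulate_binding_sites(tiles, rep(0, n), c(-Inf, 0), seed = 5L)
  expect_equal(nrow(s0), 0L)

  # b > 0: counts positively rank-correlated with RT
  rt <- runif(n, -2.5, 2.5)
  s1 <- simulate_binding_sites(tiles, rt, c(log(2), 0.5), seed = 6L)
  cnt1 <- count_sites_per_window(s1, big)
  expect_gt(cor(cnt1, rt, method = "spearman"), 0.3)

  expect_error(simulate_binding_sites(tiles, rep(1e6, n), c(1e4, 1),
                                      seed = 1L), "finite")
})

test_that("simulated expression is reproducible and independent of dRT", {
  cfg <- sim_config(n_switch_domains = 10L, seed = 14L)
  sim <- simulate_rt_dataset(layout2, cfg)
  wt <- average_windows(normalize_arrays(sim$probes), layout2)
  tiles <- genome_tiles(layout2)

  e0 <- simulate_expression(tiles, 100, lfc_sd = 0, seed = 2L)
  expect_equal(e0$log2fc, rep(0, 100))

  e1 <- simulate_expression(tiles, 500, lfc_sd = 0.5, seed = 3L)
  e2 <- simulate_expression(tiles, 500, lfc_sd = 0.5, seed = 3L)
  expect_identical(e1, e2)

  big <- simulate_expression(tiles, 20000, lfc_sd = 0.5, seed = 4L)
  r <- cor(wt$dRT[big$tile], big$log2fc, use = "complete.obs")
  expect_lt(abs(r), 0.05)
})
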