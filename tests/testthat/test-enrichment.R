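test_that("site counting is half-open and conserves the total", {
  layout <- tiny_layout(c(chr1 = 6e5, chr2 = 4e5))
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      pos = c(10000, 150000, 200000, 399999))
  cnt <- count_sites_per_window(sites, layout)
  expect_equal(cnt, c(2L, 1L, 0L, 0L, 1L))
  expect_equal(sum(cnt), nrow(sites))

  # empty site set
  empty <- data.frame(chrom = character(0), pos = numeric(0))
  expect_equal(count_sites_per_window(empty, layout), integer(5))

  # intervals are reduced to midpoints
  iv <- data.frame(chrom = "chr1", start = 199000, end = 201100)
  expect_equal(count_sites_per_window(iv, layout), c(0L, 1L, 0L, 0L, 0L))

  bad <- data.frame(chrom = "chr2", pos = 4e5)
  expect_error(count_sites_per_window(bad, layout), "chr2:400000")
})

test_that("the enrichment curve tracks the generative count-RT relationship", {
  # flat counts give a flat curve
  flat <- enrichment_curve(rep(3, 100), seq(-2, 2, length.out = 100))
  expect_equal(flat$mean, rep(3, nrow(flat)))

  # Poisson counts with a positive RT slope give a rising curve
  n <- 10000
  tiles <- data.frame(chrom = "chr1",
                      start = seq(0, by = 2e5, length.out = n),
                      end = seq(2e5, by = 2e5, length.out = n),
                      tile = seq_len(n))
  big <- make_genome_layout(c(chr1 = n * 2e5))
  set.seed(6)
  rt <- runif(n, -2.5, 2.5)
  sites <- simulate_binding_sites(tiles, rt, c(log(2), 0.5), seed = 7L)
  cnt <- count_sites_per_window(sites, big)
  curve <- enrichment_curve(cnt, rt, bandwidth = 0.5)
  expect_gt(cor(curve$mean, curve$rt, method = "spearman"), 0.9)
  expect_true(all(curve$se > 0))

  # rate independent of RT: curve flat within its standard errors
  sites0 <- simulate_binding_sites(tiles, rt, c(log(2), 0), seed = 8L)
  cnt0 <- count_sites_per_window(sites0, big)
  curve0 <- enrichment_curve(cnt0, rt, bandwidth = 0.5)
  cover <- abs(curve0$mean - mean(cnt0)) <= 4 * curve0$se
  expect_gte(mean(cover), 0.9)

  # two windows: error-free fallback
  tiny <- enrichment_curve(c(1, 5), c(-1, 1), bandwidth = 0.5, n_grid = 5)
  expect_true(all(is.finite(tiny$mean[c(1, nrow(tiny))])))
})

test_that("class means and domain projections are arithmetic", {
  calls <- data.frame(direction = c("EtoL", "EtoL", "LtoE", "none", "none"))
  cnt <- c(2, 4, 5, 1, 3)
  cm <- class_mean_sites(cnt, calls)
  expect_equal(cm$mean_sites[cm$class == "EtoL"], 3.0)
  # a per-window mean of 1.75 projects to 3.5-7.0 sites on 400-800 Kb domains
  cm2 <- class_mean_sites(c(1.75, 1.75, 5, 1, 3), calls)
  expect_equal(cm2$projected_low[cm2$class == "EtoL"], 3.5)
  expect_equal(cm2$projected_high[cm2$class == "EtoL"], 7.0)

  none_lto <- data.frame(direction = c("EtoL", "none"))
  cm3 <- class_mean_sites(c(1, 2), none_lto)
  expect_true(is.na(cm3$mean_sites[cm3$class == "LtoE"]))
})

test_that("rank-sum p-values match enumeration and the reference cases", {
  expect_equal(wilcoxon_rt_shift(1:3, 4:6), 0.1)
  expect_equal(wilcoxon_rt_shift(1, 2), 1.0)
  expect_message(p <- wilcoxon_rt_shift(c(2, 2), c(2, 2)), "tied")
  expect_equal(p, 1.0)

  set.seed(10)
  for (n1 in 1:4) for (n2 in n1:(8 - n1)) {
    x <- sample(1:6, n1, replace = TRUE)  # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(wilcoxon_rt_shift(x, y), brute_wilcox(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }

  # large-sample branch is a sane two-sided test
  set.seed(11)
  p_null <- wilcoxon_rt_shift(rnorm(30), rnorm(30))
  expect_true(p_null > 0 && p_null <= 1)
  p_shift <- wilcoxon_rt_shift(rnorm(30), rnorm(30) + 3)
  expect_lt(p_shift, 1e-6)
})

test_that("expression changes are summarised against switch classes", {
  calls <- data.frame(chrom = "chr1",
                      start = seq(0, by = 2e5, length.out = 6),
                      end = seq(2e5, by = 2e5, length.out = 6),
                      dRT = c(-1, 1, -0.9, 0.05, -0.05, 0.2),
                      direction = c("EtoL", "LtoE", "EtoL", "none", "none",
                                    "none"),
                      mean_control = c(1, -1, 1, 1, -1, 1),
                      mean_treatment = c(-0.5, 0.5, -0.4, 1.05, -1.05, 1.2))
  attr(calls, "conditions") <- c("control", "treatment")
  expr <- data.frame(gene = paste0("g", 1:6),
                     tile = c(1, 1, 2, 3, 4, 5),
                     log2fc = c(0.5, -1.2, 2.0, 0, 0.3, -0.1),
                     is_target = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  res <- expression_vs_switch(expr, calls)
  # strict two-fold rule: |0.5| and |-1.2|, |2.0| of targets in switching
  # windows -> two exceed (genes 2 and 3); gene 1 at 0.5 does not
  expect_equal(res$target_exceedance, 2L)
  expect_equal(res$n_genes_switching, 4L)
  expect_equal(res$n_targets_switching, 3L)
  expect_equal(res$class_summary$class, c("EtoL", "LtoE", "EtoE", "LtoL"))
  expect_equal(res$class_summary$n_genes, c(3L, 1L, 1L, 1L))

  # all-zero fold changes: no exceedance, R not estimable
  expr0 <- expr
  expr0$log2fc <- 0
  expect_message(res0 <- expression_vs_switch(expr0, calls), "not estimable")
  expect_equal(res0$target_exceedance, 0L)
  expect_true(is.na(res0$overall_r))

  # boundary |log2FC| exactly 1 is not "more than two-fold"
  expr1 <- expr
  expr1$log2fc <- rep(1, 6)
  res1 <- expression_vs_switch(expr1, calls)
  expect_equal(res1$target_exceedance, 0L)
})

test_that("independent expression shows no association with dRT", {
  layout <- make_genome_layout(c(chr1 = 2e7, chr2 = 2e7))
  cfg <- sim_config(n_switch_domains = 10L, seed = 23L)
  sim <- simulate_rt_dataset(layout, cfg)
  calls <- switch_test(normalize_arrays(sim$probes), layout, q_cutoff = 0.05)
  tiles <- genome_tiles(layout)
  expr <- simulate_expression(tiles, 20000, lfc_sd = 0.5, seed = 24L)
  res <- expression_vs_switch(expr, calls)
  expect_lt(abs(res$overall_r), 0.05)
  expect_gt(res$n_genes_switching, 100)
})
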