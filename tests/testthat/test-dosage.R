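test_that("a gene needs 10 expressing cells to be usable (boundary inclusive)", {
  expect_false(is_expressed(c(rep(1, 9), rep(0, 20)))$usable)
  expect_true(is_expressed(c(rep(1, 10), rep(0, 20)))$usable)
  expect_false(is_expressed(numeric(0))$usable)
})

test_that("fraction of expressing cells is simple arithmetic", {
  expect_equal(fraction_expressing(rep(c(TRUE, FALSE), c(271, 729))), 0.271)
  expect_error(fraction_expressing(logical(0)), "no cells")
})

test_that("RPSM-based expressing flags follow the observation table", {
  obs <- make_obs(c("c1", "c2", "c3"), "s1", ref = c(30L, 10L, 0L),
                  alt = c(10L, 5L, 0L))
  flags <- expressing_from_obs(obs, "G1", c("c1", "c2", "c3", "c4"))
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE, FALSE))  # rpsm 40,15,0
})

test_that("expressing fractions match the closed form at p0 = 0.9", {
  f <- log(0.9) / log(1 / 11)  # (1/11)^f = 0.9
  bp <- burst_params(f, 10)
  n <- 50000
  r2 <- mean(rowSums(simulate_allele_counts(bp, 2, n, seed = 9)) > 0)
  r3 <- mean(rowSums(simulate_allele_counts(bp, 3, n, seed = 10)) > 0)
  expect_equal(r2, 0.19, tolerance = 0.02)
  expect_equal(r3, 0.271, tolerance = 0.02)
  expect_equal(r3 / r2, 1.4263, tolerance = 0.03)
})

test_that("fold changes decompose exactly and match burst-model closed forms", {
  # identical distributions: both fold changes 1
  x <- c(rep(0, 30), rep(4, 70))
  fc0 <- fold_changes(x, x)
  expect_equal(fc0$fc_bulk, 1)
  expect_equal(fc0$fc_sc, 1)
  expect_equal(fc0$r_ratio, 1)

  # f=0.1, b=10: fc_bulk -> 1.5, fc_sc -> 1.114, r_ratio -> 1.347
  bp <- burst_params(0.1, 10)
  n <- 2e5
  d2 <- rowSums(simulate_allele_counts(bp, 2, n, seed = 11))
  d3 <- rowSums(simulate_allele_counts(bp, 3, n, seed = 12))
  fc <- fold_changes(d2, d3)
  expect_equal(fc$fc_bulk, 1.5, tolerance = 0.03)
  expect_equal(fc$fc_sc, sbar_closed(0.1, 10, 3) / sbar_closed(0.1, 10, 2),
               tolerance = 0.03)
  expect_equal(fc$r_ratio, rk_closed(0.1, 10, 3) / rk_closed(0.1, 10, 2),
               tolerance = 0.03)
  # the identity is exact bookkeeping, not an approximation
  expect_equal(fc$fc_bulk, fc$r_ratio * fc$fc_sc, tolerance = 1e-12)

  # all cells expressing: R2 = R3 = 1 and the two fold changes coincide
  fc1 <- fold_changes(c(2, 3, 4), c(3, 5, 6))
  expect_equal(fc1$r_ratio, 1)
  expect_equal(fc1$fc_bulk, fc1$fc_sc)
})

test_that("the identity fc_bulk = r_ratio * fc_sc holds for every gene", {
  sim <- small_sim(seed = 91)
  gd <- gene_dosage_table(sim$expr, truth_labels(sim))
  ok <- gd[gd$usable, ]
  expect_gt(nrow(ok), 10)
  expect_lt(max(abs(ok$fc_bulk - ok$r_ratio * ok$fc_sc)), 1e-9)
})

test_that("dosage and expression classes use the stated boundaries", {
  expect_equal(classify_dosage(c(1.5, 1.0, 0.5)),
               c("sensitive", "insensitive", "other"))
  expect_equal(classify_dosage(1.2), "other")  # boundary: not sensitive
  expect_equal(classify_expression(c(1, 3, 10, 15, 20)),
               c("low", "medium", "medium", "medium", "high"))
})

test_that("paired Wilcoxon flags the higher trisomic expressing fraction", {
  x <- seq(0.1, 0.9, length.out = 40)
  expect_warning(res0 <- compare_fractions(x, x), "zero")
  expect_equal(res0$p_value, 1)

  sim <- simulate_population(sim_config(n_genes = 60, frac_supernumerary = 1,
                                        n_genes_x = 0, n_cells_diploid = 300,
                                        n_cells_trisomic = 300,
                                        f_range = c(0.05, 0.3),
                                        cell_size_log_sd = 0, rng_seed = 6))
  gd <- gene_dosage_table(sim$expr, truth_labels(sim))
  ok <- gd[gd$usable, ]
  expect_gt(nrow(ok), 50)
  res <- compare_fractions(ok$r2, ok$r3)
  expect_lt(res$p_value, 0.05)
  expect_gt(median(ok$r3 - ok$r2), 0)
  expect_error(compare_fractions(1:3 / 10, 2:4 / 10), "at least 6")
})

test_that("Wilcoxon p-values are calibrated under the null", {
  set.seed(14)
  p <- replicate(400, {
    a <- runif(20); b <- a + rnorm(20, 0, 0.05)  # exchangeable differences
    suppressWarnings(compare_fractions(a, b)$p_value)
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_gt(mean(p), 0.4)  # roughly uniform, not skewed towards 0
})

test_that("hyperbola fit recovers the exact inverse relationship", {
  fc_sc <- seq(1, 1.5, length.out = 20)
  s <- data.frame(usable = TRUE, fc_sc = fc_sc, r_ratio = 1.5 / fc_sc)
  fit <- hyperbola_fit(s)
  expect_equal(fit$rho, -1)
  expect_equal(fit$curve(1.5), 1)
  expect_error(hyperbola_fit(data.frame(usable = TRUE, fc_sc = rep(1, 12),
                                        r_ratio = rep(1.5, 12))), "degenerate")
  expect_error(hyperbola_fit(s[1:5, ]), "at least 10")
})

test_that("burst-grid simulation bends along the hyperbola; control genes sit at 1", {
  sim <- simulate_population(sim_config(n_genes = 80, frac_supernumerary = 0.5,
                                        n_genes_x = 0, n_cells_diploid = 250,
                                        n_cells_trisomic = 250, rng_seed = 7))
  truth <- truth_labels(sim)
  sup <- unique(sim$sites$gene_id[sim$sites$chrom == "chr21"])
  ctrl <- unique(sim$sites$gene_id[sim$sites$chrom == "chr1"])

  gd_sup <- gene_dosage_table(sim$expr, truth, genes = sup)
  fit <- hyperbola_fit(gd_sup)
  expect_lt(fit$rho, 0)

  gd_ctrl <- gene_dosage_table(sim$expr, truth, genes = ctrl)
  ok <- gd_ctrl[gd_ctrl$usable, ]
  # disomic control: ratios centred at 1 (sign test non-significant)
  bt_r <- binom.test(sum(ok$r_ratio > 1), sum(ok$r_ratio != 1))
  bt_fc <- binom.test(sum(ok$fc_bulk > 1), sum(ok$fc_bulk != 1))
  expect_gt(bt_r$p.value, 0.01)
  expect_gt(bt_fc$p.value, 0.01)
  expect_equal(median(ok$r_ratio), 1, tolerance = 0.1)
  expect_equal(median(ok$fc_bulk), 1, tolerance = 0.12)
})

test_that("dosage imbalance of low-expressed genes is driven by more
           expressing cells", {
  sim <- simulate_population(sim_config(n_genes = 150, frac_supernumerary = 1,
                                        n_genes_x = 0, n_cells_diploid = 400,
                                        n_cells_trisomic = 400,
                                        cell_size_log_sd = 0, rng_seed = 8))
  gd <- gene_dosage_table(sim$expr, truth_labels(sim))
  strat <- stratify_by_expression(gd)
  med <- strat$medians
  expect_true(all(c("low", "medium", "high") %in% med$expression_class))
  r <- stats::setNames(med$median_r_ratio, med$expression_class)
  expect_gt(r["low"], r["medium"])
  expect_gt(r["medium"], r["high"])
  fc <- stats::setNames(med$median_fc_sc, med$expression_class)
  expect_gt(fc[["high"]], fc[["low"]])
  expect_equal(fc[["high"]], 1.5, tolerance = 0.1)  # p0 -> 0 limit
  expect_equal(r[["high"]], 1, tolerance = 0.1)

  # single populated class: medians only, no tests
  one <- gd[gd$usable & gd$expression_class == "low", ]
  strat1 <- stratify_by_expression(one)
  expect_null(strat1$tests)
  expect_equal(strat1$medians$expression_class, "low")
})
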