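test_that("min-max expression feature is 1 for the maximal cell", {
  expr <- matrix(c(0, 5, 10, 1, 1, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("G1", "G2"), c("c1", "c2", "c3")))
  sites <- data.frame(site_id = "s1", chrom = "chr21", pos = 100,
                      gene_id = "G1", stringsAsFactors = FALSE)
  obs <- make_obs(c("c1", "c2", "c3"), "s1", ref = c(10L, 10L, 10L),
                  alt = c(10L, 10L, 10L))
  ft <- build_features(expr, obs, sites, "chr21", cpm = FALSE)
  expect_equal(unname(ft$features[, "expr"]), c(0, 0.5, 1))
  # constant gene normalises to zero, never NaN
  sites2 <- data.frame(site_id = "s1", chrom = "chr21", pos = 100,
                       gene_id = "G2", stringsAsFactors = FALSE)
  ft2 <- build_features(expr, obs, sites2, "chr21", cpm = FALSE)
  expect_true(all(ft2$features[, "expr"] == 0))
})

test_that("double-allele estimation follows read sums with stated tie rules", {
  counts <- data.frame(
    cell_id = c("t1", "t2", "t1", "t2", "t1"),
    site_id = c("s1", "s1", "s2", "s2", "s3"),
    ref_reads = c(200L, 100L, 75L, 75L, 0L),
    alt_reads = c(100L, 50L, 80L, 70L, 0L),
    stringsAsFactors = FALSE
  )
  sites <- data.frame(site_id = c("s1", "s2", "s3", "s4"), chrom = "chr21",
                      pos = 1:4 * 100, gene_id = paste0("G", 1:4),
                      stringsAsFactors = FALSE)
  map <- estimate_double_allele(counts, sites, c("t1", "t2"), "chr21")
  expect_equal(unname(map["s1"]), "ref")    # 300 vs 150
  expect_equal(unname(map["s2"]), "ref")    # 155 vs 150
  expect_equal(unname(map["s3"]), "unknown")  # zero reads, no previous
  expect_equal(unname(map["s4"]), "unknown")  # no reads at all

  # exact tie keeps the previous assignment
  counts$alt_reads[1:2] <- c(200L, 100L)
  map2 <- estimate_double_allele(counts, sites, c("t1", "t2"), "chr21",
                                 previous = c(s1 = "alt"))
  expect_equal(unname(map2["s1"]), "alt")
  map3 <- estimate_double_allele(counts, sites, c("t1", "t2"), "chr21")
  expect_equal(unname(map3["s1"]), "ref")  # tie without previous: reference
  expect_error(estimate_double_allele(counts, sites, character(), "chr21"),
               "no cell")
})

test_that("double-allele map is accurate at paper-like depth", {
  sim <- simulate_population(sim_config(n_cells_diploid = 100,
                                        n_cells_trisomic = 100,
                                        mean_site_depth = 20,
                                        capture_efficiency = 0.3,
                                        n_genes_x = 0, rng_seed = 60))
  tri <- names(truth_labels(sim))[truth_labels(sim) == "trisomic"]
  map <- estimate_double_allele(sim$counts, sim$sites, tri, "chr21")
  da <- truth_da_map(sim)
  known <- names(map)[map != "unknown"]
  expect_gte(mean(map[known] == da[known]), 0.95)
})

test_that("mosaic classification recovers the simulated ploidy", {
  sim <- simulate_population(sim_config(n_cells_diploid = 158,
                                        n_cells_trisomic = 158,
                                        mean_site_depth = 20,
                                        capture_efficiency = 0.3,
                                        rng_seed = 83))
  truth <- truth_labels(sim)
  st <- classify_mosaic(sim$counts, sim$expr, sim$sites, sim$cells, "chr21",
                        seed = 7)
  expect_true(st$converged)
  expect_true(st$separable)
  expect_gte(mean(st$labels == truth[names(st$labels)]), 0.95)
  expect_lte(st$iterations, 100)
  expect_equal(length(st$label_changes), st$iterations)

  # a different k-means seed gives the same diploid/trisomic assignment:
  # the mapping is feature-based, not cluster-id-based
  st2 <- classify_mosaic(sim$counts, sim$expr, sim$sites, sim$cells, "chr21",
                         seed = 1234)
  expect_gte(mean(st$labels == st2$labels), 0.99)
})

test_that("recovered mosaic fraction tracks the simulated fraction", {
  for (frac in c(0.25, 0.75)) {
    n_tri <- round(200 * frac)
    sim <- simulate_population(sim_config(n_cells_diploid = 200 - n_tri,
                                          n_cells_trisomic = n_tri,
                                          mean_site_depth = 20,
                                          capture_efficiency = 0.3,
                                          n_genes_x = 0,
                                          rng_seed = 90 + n_tri))
    st <- classify_mosaic(sim$counts, sim$expr, sim$sites, sim$cells, "chr21",
                          seed = 2)
    est <- mean(st$labels == "trisomic")
    expect_lt(abs(est - frac), 0.08)
  }
})

test_that("pure diploid input is declared non-separable, no cell forced trisomic", {
  sim <- simulate_population(sim_config(n_genes = 80, n_cells_diploid = 120,
                                        n_cells_trisomic = 0, n_genes_x = 0,
                                        mean_site_depth = 50,
                                        capture_efficiency = 0.3,
                                        rng_seed = 44))
  expect_warning(
    st <- classify_mosaic(sim$counts, sim$expr, sim$sites, sim$cells, "chr21",
                          seed = 5),
    "separable|separation|trisomic"
  )
  expect_false(st$separable)
  expect_true(all(st$labels == "diploid"))
})

test_that("identical cells are flagged as constant features", {
  expr <- matrix(3, 2, 10, dimnames = list(c("G1", "G2"), paste0("c", 1:10)))
  sites <- data.frame(site_id = "s1", chrom = "chr21", pos = 100,
                      gene_id = "G1", stringsAsFactors = FALSE)
  counts <- data.frame(cell_id = paste0("c", 1:10), site_id = "s1",
                       ref_reads = 20L, alt_reads = 20L,
                       stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = paste0("c", 1:10), total_mapped_reads = 1e6,
                      stringsAsFactors = FALSE)
  expect_warning(
    st <- classify_mosaic(counts, expr, sites, cells, "chr21", seed = 1),
    "constant|separable"
  )
  expect_false(st$separable)
  expect_true(all(st$labels == "diploid"))
})

test_that("cross-validation is accurate on signal and at chance on shuffled labels", {
  sim <- simulate_population(sim_config(n_cells_diploid = 158,
                                        n_cells_trisomic = 158,
                                        mean_site_depth = 20,
                                        capture_efficiency = 0.3,
                                        rng_seed = 71))
  truth <- truth_labels(sim)
  cv <- cross_validate(sim$counts, sim$expr, sim$sites, sim$cells, truth,
                       "chr21", folds = 5, seed = 13)
  expect_gte(cv$accuracy, 0.95)
  expect_length(cv$fold_accuracy, 5)

  set.seed(3)
  shuffled <- stats::setNames(sample(truth), names(truth))
  cv0 <- cross_validate(sim$counts, sim$expr, sim$sites, sim$cells, shuffled,
                        "chr21", folds = 5, seed = 13)
  expect_lt(abs(cv0$accuracy - 0.5), 0.15)
})

test_that("classification accuracy does not degrade with deeper coverage", {
  acc <- vapply(c(4, 40), function(depth) {
    sim <- simulate_population(sim_config(n_cells_diploid = 100,
                                          n_cells_trisomic = 100,
                                          mean_site_depth = depth,
                                          capture_efficiency = 0.3,
                                          n_genes_x = 0, rng_seed = 19))
    truth <- truth_labels(sim)
    st <- classify_mosaic(sim$counts, sim$expr, sim$sites, sim$cells, "chr21",
                          seed = 4)
    mean(st$labels == truth[names(st$labels)])
  }, numeric(1))
  expect_gte(acc[2], acc[1])
})
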