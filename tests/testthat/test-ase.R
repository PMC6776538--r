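test_that("RPSM is site reads per million mapped reads", {
  expect_equal(compute_rpsm(40, 2e6), 20)
  expect_equal(compute_rpsm(0, 5e6), 0)
  expect_equal(compute_rpsm(1, 1e6), 1)
  expect_error(compute_rpsm(10, 0), "total mapped")
})

test_that("ASE formulas divide the designated allele by the total", {
  expect_equal(ase_diploid(10, 0), 1)
  expect_equal(ase_diploid(5, 5), 0.5)
  expect_equal(ase_diploid(2, 8), 0.2)
  expect_true(is.na(ase_diploid(0, 0)))
  expect_equal(ase_trisomic(20, 10), 2 / 3, tolerance = 1e-12)
  expect_equal(ase_trisomic(0, 7), 0)
  expect_true(is.na(ase_trisomic(0, 0)))
})

test_that("ASE classes partition [0,1] with inclusive 0.1/0.9 boundaries", {
  expect_equal(classify_ase(c(0, 0.05, 0.1)), rep("monoallelic_low", 3))
  expect_equal(classify_ase(c(0.9, 0.95, 1)), rep("monoallelic_high", 3))
  expect_equal(classify_ase(c(0.100001, 0.5, 0.899999)), rep("biallelic", 3))
  expect_error(classify_ase(1.2), "0, 1")
  # partition property: every value gets exactly one class
  set.seed(1)
  cls <- classify_ase(runif(500))
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("monoallelic_low", "biallelic", "monoallelic_high"))
})

test_that("coverage/RPSM filters are inclusive and monotone", {
  obs <- make_obs("c1", paste0("s", 1:3), ref = c(16L, 10L, 100L),
                  alt = c(0L, 5L, 0L))
  obs$rpsm <- c(20, 100, 19.9)
  kept <- filter_observations(obs)
  expect_equal(kept$site_id, "s1")  # boundary coverage=16, rpsm=20 retained

  set.seed(2)
  big <- make_obs(paste0("c", 1:300), "s1", ref = rpois(300, 20),
                  alt = rpois(300, 10))
  big$rpsm <- runif(300, 0, 60)
  for (mc in c(0, 10, 30)) {
    for (mr in c(0, 10, 30)) {
      a <- filter_observations(big, mc, mr)
      b <- filter_observations(big, mc + 5, mr)
      c2 <- filter_observations(big, mc, mr + 5)
      expect_true(all(b$cell_id %in% a$cell_id))
      expect_true(all(c2$cell_id %in% a$cell_id))
    }
  }
  expect_equal(nrow(filter_observations(big[0, ])), 0)
})

test_that("double-allele orientation flips alt-doubled sites", {
  obs <- make_obs(c("c1", "c2"), c("s1", "s2"), ref = c(8L, 2L), alt = c(2L, 8L))
  map <- c(s1 = "ref", s2 = "alt")
  out <- orient_to_double_allele(obs, map)
  expect_equal(out$ase, c(0.8, 0.8))
  expect_error(orient_to_double_allele(obs, c(s1 = "ref")), "unknown double allele")
  dropped <- orient_to_double_allele(obs, c(s1 = "ref"), drop_unknown = TRUE)
  expect_equal(nrow(dropped), 1)
})

test_that("MEP uses the most observed site and counts monoallelic cells", {
  # site s2 has more cellular observations than s1
  o1 <- make_obs(paste0("c", 1:40), "s1", ref = rep(20L, 40), alt = rep(20L, 40),
                 pos = 100)
  o2 <- make_obs(paste0("c", 1:60), "s2",
                 ref = c(rep(30L, 51), rep(15L, 9)),
                 alt = c(rep(0L, 51), rep(15L, 9)), pos = 200)
  mep <- compute_mep(rbind(o1, o2))
  expect_equal(mep$chosen_site, "s2")
  expect_equal(mep$n_cells_observed, 60)
  expect_equal(mep$mep, 51 / 60)
  expect_equal(mep$mep_class, "monoallelic")

  # tie broken to the lowest position
  o3 <- make_obs(paste0("c", 1:40), "s3", ref = rep(20L, 40), alt = rep(20L, 40),
                 pos = 50)
  mep2 <- compute_mep(rbind(o1, o3))
  expect_equal(mep2$chosen_site, "s3")
  expect_equal(mep2$mep, 0)  # all biallelic

  expect_equal(nrow(compute_mep(o1[0, ])), 0)
})

test_that("MEP classes follow the 20/80 boundaries", {
  expect_equal(classify_gene_mep(0.85), "monoallelic")
  expect_equal(classify_gene_mep(0.5), "intermediate")
  expect_equal(classify_gene_mep(0.1), "biallelic")
  expect_equal(classify_gene_mep(c(0.2, 0.8)), rep("intermediate", 2))
})

test_that("histogram summary partitions observations", {
  obs <- make_obs(paste0("c", 1:10), "s1",
                  ref = c(rep(40L, 3), rep(0L, 2), rep(20L, 5)),
                  alt = c(rep(0L, 3), rep(40L, 2), rep(20L, 5)))
  s <- ase_histogram_summary(obs)
  expect_equal(s$fraction_da_monoallelic, 0.3)
  expect_equal(s$fraction_sa_monoallelic, 0.2)
  expect_equal(s$fraction_monoallelic, 0.5)
  expect_equal(s$mean_biallelic_ase, 0.5)

  all_high <- make_obs(paste0("c", 1:5), "s1", ref = rep(10L, 5), alt = rep(0L, 5))
  s2 <- ase_histogram_summary(all_high)
  expect_equal(s2$fraction_monoallelic, 1)
  expect_true(is.na(s2$mean_biallelic_ase))
  expect_error(ase_histogram_summary(all_high[0, ]), "no ASE")
})

test_that("ase_table validates ids and drops zero-coverage rows", {
  sim <- small_sim(seed = 31)
  obs <- ase_table(sim$counts, sim$sites, sim$cells)
  expect_true(all(obs$coverage > 0))
  expect_true(all(obs$ase >= 0 & obs$ase <= 1))
  bad <- sim$counts
  bad$site_id[1] <- "nope"
  expect_error(ase_table(bad, sim$sites, sim$cells), "unknown site")
})

test_that("gene MEP falls with expression level (negative Spearman)", {
  sim <- simulate_population(sim_config(n_genes = 120, frac_supernumerary = 0,
                                        n_cells_diploid = 150,
                                        n_cells_trisomic = 0, n_genes_x = 0,
                                        rng_seed = 55))
  obs <- filter_observations(ase_table(sim$counts, sim$sites, sim$cells))
  mep <- compute_mep(obs)
  expr_mean <- rowMeans(sim$expr)[mep$gene_id]
  ct <- suppressWarnings(cor.test(mep$mep, expr_mean, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("trisomic biallelic ASE sits above 0.5, towards the double allele", {
  sim <- simulate_population(sim_config(n_genes = 80, frac_supernumerary = 1,
                                        n_cells_diploid = 0,
                                        n_cells_trisomic = 200, n_genes_x = 0,
                                        rng_seed = 77))
  obs <- filter_observations(ase_table(sim$counts, sim$sites, sim$cells))
  ot <- orient_to_double_allele(obs, truth_da_map(sim), drop_unknown = TRUE)
  s <- ase_histogram_summary(ot)
  expect_gt(s$mean_biallelic_ase, 0.55)
  expect_gt(s$fraction_da_monoallelic, s$fraction_sa_monoallelic)
})

test_that("monoallelic partition approaches the 2:1 copy-number split for
           rarely bursting genes", {
  sim <- simulate_population(sim_config(n_genes = 150, frac_supernumerary = 1,
                                        n_cells_diploid = 0,
                                        n_cells_trisomic = 400, n_genes_x = 0,
                                        f_range = c(0.05, 0.2),
                                        cell_size_log_sd = 0, rng_seed = 5))
  obs <- filter_observations(ase_table(sim$counts, sim$sites, sim$cells))
  ot <- orient_to_double_allele(obs, truth_da_map(sim), drop_unknown = TRUE)
  s <- ase_histogram_summary(ot)
  sa_share <- s$fraction_sa_monoallelic / s$fraction_monoallelic
  expect_equal(sa_share, 1 / 3, tolerance = 0.05)
  expect_equal(s$fraction_da_monoallelic / s$fraction_sa_monoallelic, 2,
               tolerance = 0.15)
})
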