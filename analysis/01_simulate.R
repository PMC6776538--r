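#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic study populations.
#
# (a) "deep": a deep full-length-protocol mosaic population (1000 diploid +
#     1000 trisomic cells, 200 autosomal genes over the burst-parameter grid,
#     100 X-linked genes, 5% doublets) used for the ASE histograms, MEP and
#     dosage decomposition stages.
# (b) "bench316": the 316-cell half-trisomic benchmark at paper-like
#     coverage (mean site depth 20, capture efficiency 0.3) used to measure
#     classifier accuracy.
#
# Everything downstream reads the TSV/VCF/YAML artefacts written here.

library(mosaicASE)

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg_deep <- sim_config(
  n_genes = 200, n_cells_diploid = 1000, n_cells_trisomic = 1000,
  doublet_rate = 0.05, rng_seed = 20260901
)
sim_deep <- simulate_population(cfg_deep)
write_sim(sim_deep, file.path(outdir, "deep"))
message(sprintf("deep population: %d cells (%d doublets), %d sites, %d allele-count rows",
                nrow(sim_deep$cells),
                sum(sim_deep$truth$cells$ploidy == "doublet"),
                nrow(sim_deep$sites), nrow(sim_deep$counts)))

cfg_bench <- sim_config(
  n_cells_diploid = 158, n_cells_trisomic = 158,
  mean_site_depth = 20, capture_efficiency = 0.3, rng_seed = 20260902
)
sim_bench <- simulate_population(cfg_bench)
write_sim(sim_bench, file.path(outdir, "bench316"))
message(sprintf("benchmark population: %d cells, %d supernumerary genes",
                nrow(sim_bench$cells),
                sum(sim_bench$truth$sites$double_allele != "none")))
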