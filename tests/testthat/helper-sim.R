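# Shared fixtures, all generated in code.

# closed-form per-allele zero probability and derived quantities
p0_closed <- function(f, b) (1 / (1 + b))^f
rk_closed <- function(f, b, k) 1 - p0_closed(f, b)^k
sbar_closed <- function(f, b, k) k * f * b / rk_closed(f, b, k)

# a small mosaic population used by several files
small_sim <- function(seed = 42, ...) {
  simulate_population(sim_config(
    n_genes = 60, n_cells_diploid = 80, n_cells_trisomic = 80,
    n_genes_x = 60, rng_seed = seed, ...
  ))
}

truth_labels <- function(sim) {
  stats::setNames(sim$truth$cells$ploidy, sim$truth$cells$cell_id)
}

truth_da_map <- function(sim) {
  da <- stats::setNames(sim$truth$sites$double_allele, sim$truth$sites$site_id)
  da[da != "none"]
}

# hand-built ASE observation table
make_obs <- function(cell_id, site_id, ref, alt, gene_id = "G1",
                     chrom = "chr21", pos = 100, total_mapped = 1e6) {
  data.frame(
    cell_id = cell_id, site_id = site_id, gene_id = gene_id, chrom = chrom,
    pos = pos, ref_reads = ref, alt_reads = alt, coverage = ref + alt,
    rpsm = (ref + alt) / total_mapped * 1e6,
    ase = ifelse(ref + alt > 0, ref / (ref + alt), NA_real_),
    stringsAsFactors = FALSE
  )
}
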