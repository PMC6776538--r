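#!/usr/bin/env Rscript
# Stage 4: allele-specific expression histograms and MEP classes on the deep
# population (doublets removed, truth ploidy labels: the genome-matched
# setting where ploidy is known per sample).
#
# ASE per cell and heterozygous site, coverage >= 16 reads and RPSM >= 20;
# trisomic supernumerary sites oriented to the double allele. Key summaries:
# the monoallelic fractions, the DA:SA monoallelic ratio, the mean of the
# biallelic ASE distribution per ploidy, and the (negative) correlation of
# gene MEP with expression level.

library(mosaicASE)

datadir <- "results/data/deep"
outdir <- "results/tables"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sites <- read_sites(file.path(datadir, "het_sites.vcf"),
                    gene_map = file.path(datadir, "gene_map.tsv"))
counts <- read_counts(file.path(datadir, "allele_counts.tsv"))
cells <- read.delim(file.path(datadir, "cells.tsv"))
truth <- read.delim(file.path(datadir, "truth_cells.tsv"))
truth_sites <- read.delim(file.path(datadir, "truth_sites.tsv"))
expr <- read_expression(file.path(datadir, "expression.tsv"))

keep <- truth$cell_id[truth$ploidy != "doublet"]
lab <- setNames(truth$ploidy, truth$cell_id)[keep]
obs <- filter_observations(
  ase_table(counts[counts$cell_id %in% keep, ], sites,
            cells[cells$cell_id %in% keep, ]))
da_map <- setNames(truth_sites$double_allele, truth_sites$site_id)
da_map <- da_map[da_map != "none"]

tri <- names(lab)[lab == "trisomic"]
obs_tri21 <- orient_to_double_allele(
  obs[obs$cell_id %in% tri & obs$chrom == "chr21", ], da_map)
obs_dip <- obs[!obs$cell_id %in% tri & obs$chrom != "chrX", ]

s_tri <- ase_histogram_summary(obs_tri21)
s_dip <- ase_histogram_summary(obs_dip)
message(sprintf(
  "trisomic chr21: %.1f%% monoallelic; DA-only/SA-only ratio %.2f; biallelic mean %.3f (n=%d)",
  100 * s_tri$fraction_monoallelic,
  s_tri$fraction_da_monoallelic / s_tri$fraction_sa_monoallelic,
  s_tri$mean_biallelic_ase, s_tri$n_obs))
message(sprintf(
  "diploid autosomes: %.1f%% monoallelic; biallelic mean %.3f (n=%d)",
  100 * s_dip$fraction_monoallelic, s_dip$mean_biallelic_ase, s_dip$n_obs))

hist_tab <- rbind(
  data.frame(group = "trisomic_chr21", as.data.frame(s_tri[1:4]), n_obs = s_tri$n_obs),
  data.frame(group = "diploid_autosomes", as.data.frame(s_dip[1:4]), n_obs = s_dip$n_obs)
)
write.table(hist_tab, file.path(outdir, "ase_histogram_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# per-gene MEP on the trisomic cells' supernumerary sites, and its relation
# to expression level
mep <- compute_mep(obs_tri21)
mean_expr <- rowMeans(expr[, tri])[mep$gene_id]
ct <- suppressWarnings(cor.test(mep$mep, mean_expr, method = "spearman"))
message(sprintf("MEP vs expression: Spearman rho = %.2f (p = %.2g, n = %d genes)",
                ct$estimate, ct$p.value, nrow(mep)))
message(sprintf("MEP classes: %s",
                paste(names(table(mep$mep_class)), table(mep$mep_class),
                      sep = "=", collapse = ", ")))
mep$mean_expression <- mean_expr
write.table(mep, file.path(outdir, "mep_trisomic_chr21.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# full per-observation ASE table for downstream plotting
write.table(rbind(cbind(obs_tri21, group = "trisomic_chr21"),
                  cbind(obs_dip, group = "diploid_autosomes")),
            file.path(outdir, "ase_observations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  d <- rbind(data.frame(ase = obs_tri21$ase, group = "trisomic chr21 (DA)"),
             data.frame(ase = obs_dip$ase, group = "diploid autosomes (REF)"))
  p <- ggplot(d, aes(ase, fill = group)) +
    geom_histogram(bins = 50, position = "identity", alpha = 0.6) +
    facet_wrap(~group, scales = "free_y") +
    labs(x = "allele-specific expression", y = "cell x site observations") +
    theme_bw() + theme(legend.position = "none")
  ggsave("results/figures/ase_histograms.png", p, width = 8, height = 3.5, dpi = 150)
}
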