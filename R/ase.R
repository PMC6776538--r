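# Allele-specific expression per cell and heterozygous site.
#
# Diploid regions:   ASE = ref reads / (ref + alt reads).
# Trisomic regions:  ASE = double-allele reads / (double + single allele reads),
# where the double allele (DA) is the allele present in two of the three
# copies (genotype ABB or BAA) and the single/unique allele (SA) the other.
# ASE <= 0.1 is called monoallelic expression of the ALT (or single) allele,
# ASE >= 0.9 monoallelic expression of the REF (or double) allele, both
# boundaries inclusive; anything strictly between is biallelic.

#' Reads per site per million mapped reads (RPSM)
#'
#' Site coverage scaled by the cell's total mapped reads, the allele-dropout
#' guard used at the default threshold of 20.
#'
#' @param site_reads Read count at the site (vectorised).
#' @param total_mapped_reads Total mapped reads in the cell (vectorised).
#' @return Numeric RPSM values.
#' @export
#' @examples
#' compute_rpsm(40, 2e6) # 20
compute_rpsm <- function(site_reads, total_mapped_reads) {
  if (any(total_mapped_reads <= 0)) {
    stop("total mapped reads per cell must be > 0", call. = FALSE)
  }
  site_reads / total_mapped_reads * 1e6
}

#' ASE of a diploid heterozygous site
#'
#' @param ref_reads,alt_reads Read counts supporting each allele (vectorised).
#' @return `ref_reads / (ref_reads + alt_reads)`; `NA` where the total is 0
#'   (such observations are dropped downstream, never imputed).
#' @export
ase_diploid <- function(ref_reads, alt_reads) {
  tot <- ref_reads + alt_reads
  ifelse(tot > 0, ref_reads / tot, NA_real_)
}

#' ASE of a trisomic heterozygous site
#'
#' @param da_reads,sa_reads Reads supporting the double and the single
#'   (unique) allele (vectorised).
#' @return `da_reads / (da_reads + sa_reads)`; `NA` where the total is 0.
#' @export
ase_trisomic <- function(da_reads, sa_reads) {
  tot <- da_reads + sa_reads
  ifelse(tot > 0, da_reads / tot, NA_real_)
}

#' Classify an ASE value
#'
#' @param ase ASE values in \[0, 1\].
#' @param cutoffs Monoallelic cutoffs, default `c(0.1, 0.9)`, both inclusive.
#' @return Character vector: `"monoallelic_low"` (<= 0.1), `"biallelic"`
#'   (open interval) or `"monoallelic_high"` (>= 0.9).
#' @export
classify_ase <- function(ase, cutoffs = c(0.1, 0.9)) {
  if (any(ase < 0 | ase > 1, na.rm = TRUE)) {
    stop("ASE values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_character_, length(ase))
  out[ase <= cutoffs[1]] <- "monoallelic_low"
  out[ase >= cutoffs[2]] <- "monoallelic_high"
  out[ase > cutoffs[1] & ase < cutoffs[2]] <- "biallelic"
  out
}

#' Build the per-observation ASE table
#'
#' One row per (cell, site) with coverage > 0: reference-oriented ASE,
#' coverage and RPSM. Orientation to the double allele is applied afterwards
#' with [orient_to_double_allele()] once a double-allele map is available.
#'
#' @param counts Allele count table (`cell_id`, `site_id`, `ref_reads`,
#'   `alt_reads`).
#' @param sites Site annotation table (must carry `site_id`, `chrom`, `pos`,
#'   `gene_id`).
#' @param cells Cell table with `cell_id` and `total_mapped_reads`.
#' @return data.frame: cell_id, site_id, gene_id, chrom, pos, ref_reads,
#'   alt_reads, coverage, rpsm, ase (reference fraction).
#' @export
ase_table <- function(counts, sites, cells) {
  i <- match(counts$site_id, sites$site_id)
  if (anyNA(i)) stop("counts reference unknown site ids", call. = FALSE)
  j <- match(counts$cell_id, cells$cell_id)
  if (anyNA(j)) stop("counts reference unknown cell ids", call. = FALSE)
  cov <- counts$ref_reads + counts$alt_reads
  obs <- data.frame(
    cell_id = counts$cell_id, site_id = counts$site_id,
    gene_id = sites$gene_id[i], chrom = sites$chrom[i], pos = sites$pos[i],
    ref_reads = counts$ref_reads, alt_reads = counts$alt_reads,
    coverage = cov,
    rpsm = compute_rpsm(cov, cells$total_mapped_reads[j]),
    ase = ase_diploid(counts$ref_reads, counts$alt_reads),
    stringsAsFactors = FALSE
  )
  obs[!is.na(obs$ase), , drop = FALSE]
}

#' Re-orient reference-based ASE to the double allele
#'
#' For sites whose double allele is `alt`, ASE becomes `1 - ase`; for `ref`
#' it is unchanged. Sites with unknown double allele raise an error unless
#' `drop_unknown = TRUE`.
#'
#' @param obs ASE observation table from [ase_table()].
#' @param double_allele_map Named character vector (site_id -> "ref"/"alt"),
#'   or a data.frame with columns `site_id` and `double_allele`.
#' @param drop_unknown Drop observations at sites missing from the map.
#' @return `obs` with `ase` oriented to the double allele.
#' @export
orient_to_double_allele <- function(obs, double_allele_map, drop_unknown = FALSE) {
  if (is.data.frame(double_allele_map)) {
    double_allele_map <- stats::setNames(double_allele_map$double_allele,
                                         double_allele_map$site_id)
  }
  da <- double_allele_map[obs$site_id]
  bad <- is.na(da) | !da %in% c("ref", "alt")
  if (any(bad)) {
    if (!drop_unknown) stop("unknown double allele for ",
                            sum(bad), " observation(s)", call. = FALSE)
    obs <- obs[!bad, , drop = FALSE]
    da <- da[!bad]
  }
  obs$ase <- ifelse(da == "alt", 1 - obs$ase, obs$ase)
  obs
}

#' Coverage and RPSM filter
#'
#' Retains observations with `coverage >= min_coverage` and
#' `rpsm >= min_rpsm`, both boundaries inclusive. Raising either threshold
#' never adds observations.
#'
#' @param obs ASE observation table.
#' @param min_coverage Minimum reads at the site (default 16).
#' @param min_rpsm Minimum RPSM (default 20).
#' @return The filtered table.
#' @export
filter_observations <- function(obs, min_coverage = 16, min_rpsm = 20) {
  obs[obs$coverage >= min_coverage & obs$rpsm >= min_rpsm, , drop = FALSE]
}

#' Monoallelic expression prevalence (MEP) per gene
#'
#' For each gene, the heterozygous site with the most cellular ASE
#' observations is chosen (ties broken to the lowest genomic position) and
#' MEP is the fraction of that site's cells with a monoallelic call
#' (ASE <= 0.1 or >= 0.9).
#'
#' @param obs Filtered ASE observation table.
#' @param cutoffs Monoallelic ASE cutoffs, default `c(0.1, 0.9)`.
#' @param mep_cutoffs MEP class boundaries, default `c(0.2, 0.8)`.
#' @return data.frame: gene_id, chosen_site, n_cells_observed, mep, mep_class.
#' @export
compute_mep <- function(obs, cutoffs = c(0.1, 0.9), mep_cutoffs = c(0.2, 0.8)) {
  if (nrow(obs) == 0) {
    return(data.frame(gene_id = character(), chosen_site = character(),
                      n_cells_observed = integer(), mep = numeric(),
                      mep_class = character(), stringsAsFactors = FALSE))
  }
  tab <- stats::aggregate(cell_id ~ site_id + gene_id + pos, obs,
                          FUN = function(x) length(unique(x)))
  names(tab)[names(tab) == "cell_id"] <- "n_obs"
  tab <- tab[order(tab$gene_id, -tab$n_obs, tab$pos), ]
  chosen <- tab[!duplicated(tab$gene_id), ]
  res <- lapply(seq_len(nrow(chosen)), function(i) {
    o <- obs[obs$site_id == chosen$site_id[i], ]
    mono <- o$ase <= cutoffs[1] | o$ase >= cutoffs[2]
    data.frame(
      gene_id = chosen$gene_id[i], chosen_site = chosen$site_id[i],
      n_cells_observed = nrow(o), mep = mean(mono),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  res$mep_class <- classify_gene_mep(res$mep, mep_cutoffs)
  res
}

#' Classify a gene by its MEP
#'
#' @param mep MEP values in \[0, 1\].
#' @param mep_cutoffs Boundaries, default `c(0.2, 0.8)`: monoallelic genes
#'   have MEP > 0.8, biallelic genes MEP < 0.2, intermediate genes the closed
#'   interval in between.
#' @return Character vector of classes.
#' @export
classify_gene_mep <- function(mep, mep_cutoffs = c(0.2, 0.8)) {
  stopifnot(all(mep >= 0 & mep <= 1, na.rm = TRUE))
  ifelse(mep > mep_cutoffs[2], "monoallelic",
         ifelse(mep < mep_cutoffs[1], "biallelic", "intermediate"))
}

#' Summary of an ASE histogram
#'
#' @param obs Filtered ASE observation table (orient to the double allele
#'   first for trisomic regions).
#' @param cutoffs Monoallelic cutoffs, default `c(0.1, 0.9)`.
#' @return List: `fraction_monoallelic` (total), `fraction_da_monoallelic`
#'   (ASE >= 0.9: the double -- or reference -- allele only),
#'   `fraction_sa_monoallelic` (ASE <= 0.1: the single -- or alternative --
#'   allele only), `mean_biallelic_ase` (mean over 0.1 < ASE < 0.9, `NA` when
#'   no biallelic observation exists) and `n_obs`.
#' @export
ase_histogram_summary <- function(obs, cutoffs = c(0.1, 0.9)) {
  if (nrow(obs) == 0) stop("no ASE observations", call. = FALSE)
  lo <- obs$ase <= cutoffs[1]
  hi <- obs$ase >= cutoffs[2]
  bi <- !lo & !hi
  list(
    fraction_monoallelic = mean(lo | hi),
    fraction_da_monoallelic = mean(hi),
    fraction_sa_monoallelic = mean(lo),
    mean_biallelic_ase = if (any(bi)) mean(obs$ase[bi]) else NA_real_,
    n_obs = nrow(obs)
  )
}
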