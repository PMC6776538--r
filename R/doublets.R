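# Doublet detection in female samples from X-chromosome haplotype expression.
#
# Random X inactivation makes each female singlet express one X haplotype;
# across heterozygous X sites the per-cell reference-allele ratios form a
# haplotype "pattern". Two cells on the same haplotype correlate near +1,
# cells on opposite haplotypes near -1. A doublet expresses both haplotypes
# at once, so its pattern is a noisy mixture whose absolute correlation to
# either haplotype group drops well below the singlet regime.

#' GRCh37 pseudoautosomal regions of the X chromosome
#'
#' Matrix with one row per region (`start`, `end`), 1-based inclusive.
#' @export
PAR_GRCH37 <- matrix(c(60001, 2699520, 154931044, 155260560),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("PAR1", "PAR2"), c("start", "end")))

#' Per-cell X-haplotype expression profiles
#'
#' Reference-allele ratio at every informative heterozygous X site, excluding
#' pseudoautosomal regions and known escapee genes.
#'
#' @param obs ASE observation table (reference-oriented; apply coverage
#'   filters beforehand if desired).
#' @param sites Site annotation table.
#' @param escapees Character vector of escapee gene ids to exclude.
#' @param par Matrix of PAR intervals (default [PAR_GRCH37]).
#' @param x_chrom Name of the X chromosome in `sites` (default "chrX").
#' @return Cells x sites numeric matrix of reference ratios, `NA` where a
#'   cell has no coverage. Cells without any informative site are dropped
#'   with a warning. Returns a 0-row matrix for samples without heterozygous
#'   X sites (male or X-homozygous samples: the screen is a no-op).
#' @export
x_profiles <- function(obs, sites, escapees = character(), par = PAR_GRCH37,
                       x_chrom = "chrX") {
  xs <- sites[sites$chrom == x_chrom, , drop = FALSE]
  in_par <- rep(FALSE, nrow(xs))
  for (r in seq_len(nrow(par))) {
    in_par <- in_par | (xs$pos >= par[r, "start"] & xs$pos <= par[r, "end"])
  }
  xs <- xs[!in_par & !(xs$gene_id %in% escapees), , drop = FALSE]
  if (nrow(xs) == 0) {
    message("no informative heterozygous X site; doublet screen skipped")
    return(matrix(numeric(), 0, 0))
  }
  o <- obs[obs$site_id %in% xs$site_id, , drop = FALSE]
  cells <- unique(o$cell_id)
  prof <- matrix(NA_real_, length(cells), nrow(xs),
                 dimnames = list(cells, xs$site_id))
  prof[cbind(match(o$cell_id, cells), match(o$site_id, xs$site_id))] <- o$ase
  n_inf <- rowSums(!is.na(prof))
  if (any(n_inf == 0)) {
    warning(sum(n_inf == 0), " cell(s) without informative X sites excluded ",
            "from the doublet screen")
    prof <- prof[n_inf > 0, , drop = FALSE]
  }
  prof
}

#' Flag doublets from X-haplotype profiles
#'
#' Pairwise Pearson correlations between cell profiles are computed on shared
#' informative sites (at least `min_shared`); cells are grouped into the two
#' haplotype clusters by average-linkage hierarchical clustering of the
#' correlation distance (1 - r). A cell is flagged as a doublet when its
#' median absolute correlation to *both* haplotype groups falls inside
#' `band` -- i.e. away from the +/-1 regime of concordant and discordant
#' singlets, in the neighbourhood of 0.5 where mixtures of the two haplotypes
#' land.
#'
#' @param profiles Cells x sites matrix from [x_profiles()].
#' @param band Absolute-correlation band flagged as doublet, default
#'   `c(0, 0.75)`: the lower edge sits at 0 because a doublet with near-equal
#'   parental contributions is correlated with *neither* haplotype pattern
#'   (its per-site mixture ratios carry little haplotype signal), while every
#'   clean singlet is strongly correlated (|r| near 1) with its own group.
#' @param min_shared Minimum shared informative sites for a pairwise
#'   correlation (default 10).
#' @return A list: `is_doublet` (named logical), `median_abs_cor` (cells x 2
#'   matrix of median absolute correlations to the two haplotype groups),
#'   `groups` (haplotype group per cell), `cor` (pairwise correlation
#'   matrix).
#' @export
detect_doublets <- function(profiles, band = c(0, 0.75), min_shared = 10) {
  n <- nrow(profiles)
  if (n == 0) {
    return(list(is_doublet = stats::setNames(logical(), character()),
                median_abs_cor = NULL, groups = NULL, cor = NULL))
  }
  if (n < 3) stop("need at least 3 cells with X profiles", call. = FALSE)
  shared <- crossprod(!is.na(t(profiles)) * 1)
  cm <- suppressWarnings(stats::cor(t(profiles), use = "pairwise.complete.obs"))
  cm[shared < min_shared] <- NA
  diag(cm) <- 1
  if (all(is.na(cm[upper.tri(cm)])) || stats::sd(cm[upper.tri(cm)], na.rm = TRUE) == 0) {
    # all profiles effectively identical: nothing to flag
    return(list(is_doublet = stats::setNames(rep(FALSE, n), rownames(profiles)),
                median_abs_cor = NULL, groups = NULL, cor = cm))
  }
  d <- 1 - cm
  d[is.na(d)] <- 1  # uninformative pairs treated as uncorrelated
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, k = 2)
  med <- t(vapply(seq_len(n), function(i) {
    vapply(1:2, function(g) {
      others <- setdiff(which(grp == g), i)
      v <- abs(cm[i, others])
      if (all(is.na(v)) || length(v) == 0) NA_real_ else stats::median(v, na.rm = TRUE)
    }, numeric(1))
  }, numeric(2)))
  dimnames(med) <- list(rownames(profiles), c("group1", "group2"))
  flag <- !is.na(med[, 1]) & !is.na(med[, 2]) &
    med[, 1] >= band[1] & med[, 1] <= band[2] &
    med[, 2] >= band[1] & med[, 2] <= band[2]
  list(is_doublet = stats::setNames(flag, rownames(profiles)),
       median_abs_cor = med,
       groups = stats::setNames(grp, rownames(profiles)),
       cor = cm)
}
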