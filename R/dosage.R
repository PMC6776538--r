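# Decomposition of gene dosage imbalance.
#
# For a gene with k copies, writing s for its expression across cells, R_k
# for the fraction of cells expressing it and s_bar_k for the zero-truncated
# mean among expressing cells, copy-number-proportional bursting implies
#
#   E(s_k) / E(s_2)  =  (R_k * s_bar_k) / (R_2 * s_bar_2)  =  k / 2 ,
#
# so the bulk fold change (1.5 in trisomy) splits multiplicatively into the
# ratio of expressing-cell fractions R_3/R_2 and the single-cell fold change
# s_bar_3/s_bar_2, which are inversely proportional along the hyperbola
# r_ratio = 1.5 / fc_sc. Low-expressed genes sit at the high-r_ratio end
# (dosage imbalance driven by more cells expressing), highly expressed genes
# at fc_sc ~ 1.5 (more transcript per cell).

#' Per-cell expressing flags for one gene
#'
#' A cell expresses the gene when its value exceeds `threshold` (preset
#' `"transcripts"`: > 0 on transcript counts; `"droplet"`: > 5 on UMI
#' counts). For C1-like data use the RPSM rule on the observation table
#' instead ([expressing_from_obs()]). The gene is usable when at least
#' `min_cells` cells express it overall.
#'
#' @param values Numeric vector of per-cell expression values.
#' @param threshold Expression threshold (strict inequality).
#' @param min_cells Minimum expressing cells for the gene to be usable
#'   (default 10).
#' @return List: `expressed` (logical per cell), `usable` (flag).
#' @export
is_expressed <- function(values, threshold = 0, min_cells = 10) {
  expressed <- values > threshold
  list(expressed = expressed, usable = sum(expressed) >= min_cells)
}

#' Expressing flags from ASE observations (RPSM rule)
#'
#' A cell expresses a gene when it has an observation at the gene's chosen
#' site with RPSM >= `min_rpsm` (the C1 criterion).
#'
#' @param obs ASE observation table.
#' @param gene_id Gene to evaluate.
#' @param cell_ids All QC-passed cells of the sample.
#' @param min_rpsm RPSM threshold (default 20).
#' @return Named logical vector over `cell_ids`.
#' @export
expressing_from_obs <- function(obs, gene_id, cell_ids, min_rpsm = 20) {
  o <- obs[obs$gene_id == gene_id & obs$rpsm >= min_rpsm, , drop = FALSE]
  stats::setNames(cell_ids %in% o$cell_id, cell_ids)
}

#' Fraction of cells expressing a gene
#'
#' @param expressed Logical vector of per-cell expressing flags for the cells
#'   of one ploidy.
#' @return R_k, the expressing fraction.
#' @export
fraction_expressing <- function(expressed) {
  if (length(expressed) == 0) stop("no cells of this ploidy", call. = FALSE)
  mean(expressed)
}

#' Bulk and single-cell fold changes for one gene
#'
#' `fc_bulk` is the ratio of means over *all* cells (non-expressing cells
#' contribute zero), `fc_sc` the ratio of zero-truncated means over
#' expressing cells only. By construction
#' `fc_bulk = (r3 / r2) * fc_sc` exactly.
#'
#' @param diploid,trisomic Numeric per-cell expression vectors.
#' @param expressed_diploid,expressed_trisomic Logical expressing flags
#'   (default: value > 0).
#' @return List: fc_bulk, fc_sc, r2, r3, r_ratio, mean_diploid (bulk diploid
#'   mean), usable (FALSE when a required mean is zero or no cell expresses).
#' @export
fold_changes <- function(diploid, trisomic,
                         expressed_diploid = diploid > 0,
                         expressed_trisomic = trisomic > 0) {
  r2 <- fraction_expressing(expressed_diploid)
  r3 <- fraction_expressing(expressed_trisomic)
  m2 <- mean(diploid * expressed_diploid)
  m3 <- mean(trisomic * expressed_trisomic)
  if (r2 == 0 || r3 == 0 || m2 == 0) {
    return(list(fc_bulk = NA_real_, fc_sc = NA_real_, r2 = r2, r3 = r3,
                r_ratio = NA_real_, mean_diploid = m2, usable = FALSE))
  }
  s2 <- m2 / r2  # zero-truncated means
  s3 <- m3 / r3
  list(fc_bulk = m3 / m2, fc_sc = s3 / s2, r2 = r2, r3 = r3,
       r_ratio = r3 / r2, mean_diploid = m2, usable = TRUE)
}

#' Dosage-sensitivity class of a fold change
#'
#' @param fc Fold change values (> 0).
#' @param sensitive_threshold Sensitive above this (default 1.2).
#' @param insensitive_band Open interval called insensitive
#'   (default `c(0.8, 1.2)`).
#' @return `"sensitive"`, `"insensitive"` or `"other"` per value.
#' @export
classify_dosage <- function(fc, sensitive_threshold = 1.2,
                            insensitive_band = c(0.8, 1.2)) {
  ifelse(is.na(fc), NA_character_,
         ifelse(fc > sensitive_threshold, "sensitive",
                ifelse(fc > insensitive_band[1] & fc < insensitive_band[2],
                       "insensitive", "other")))
}

#' Expression class from the diploid bulk mean
#'
#' @param mean_expr Diploid mean expression per gene.
#' @param boundaries Class boundaries, default `c(3, 15)`: low < 3,
#'   medium 3--15, high > 15 (FPKM-scale units).
#' @return `"low"`, `"medium"` or `"high"` per gene.
#' @export
classify_expression <- function(mean_expr, boundaries = c(3, 15)) {
  ifelse(mean_expr < boundaries[1], "low",
         ifelse(mean_expr > boundaries[2], "high", "medium"))
}

#' Per-gene dosage decomposition table
#'
#' @param expr Genes x cells expression matrix.
#' @param labels Named character vector of per-cell ploidy labels
#'   ("diploid"/"trisomic").
#' @param genes Genes to evaluate (default all rows).
#' @param threshold Expressing threshold on `expr` (strict; default 0,
#'   droplet preset: 5).
#' @param min_cells Minimum expressing cells overall (default 10).
#' @param expr_boundaries Expression class boundaries (default `c(3, 15)`).
#' @param mep Optional MEP table from [compute_mep()]; merged by gene.
#' @return data.frame with one row per usable gene: gene_id, r2, r3, r_ratio,
#'   fc_bulk, fc_sc, mean_diploid, expression_class, dosage_class (on
#'   fc_bulk), dosage_class_sc (on fc_sc) and, when supplied, mep and
#'   mep_class. Genes failing the usability rules are reported with
#'   `usable = FALSE` and NA statistics.
#' @export
gene_dosage_table <- function(expr, labels, genes = rownames(expr),
                              threshold = 0, min_cells = 10,
                              expr_boundaries = c(3, 15), mep = NULL) {
  labels <- labels[colnames(expr)]
  dip <- names(labels)[labels == "diploid"]
  tri <- names(labels)[labels == "trisomic"]
  if (length(dip) == 0 || length(tri) == 0) {
    stop("need cells of both ploidies", call. = FALSE)
  }
  rows <- lapply(genes, function(g) {
    d <- expr[g, dip]
    t3 <- expr[g, tri]
    ed <- is_expressed(d, threshold, min_cells)
    et <- is_expressed(t3, threshold, min_cells)
    fc <- fold_changes(d, t3, ed$expressed, et$expressed)
    usable <- fc$usable && (sum(ed$expressed) + sum(et$expressed) >= min_cells)
    data.frame(gene_id = g, r2 = fc$r2, r3 = fc$r3,
               r_ratio = if (usable) fc$r_ratio else NA_real_,
               fc_bulk = if (usable) fc$fc_bulk else NA_real_,
               fc_sc = if (usable) fc$fc_sc else NA_real_,
               mean_diploid = fc$mean_diploid, usable = usable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$expression_class <- classify_expression(out$mean_diploid, expr_boundaries)
  out$dosage_class <- classify_dosage(out$fc_bulk)
  out$dosage_class_sc <- classify_dosage(out$fc_sc)
  if (!is.null(mep)) {
    i <- match(out$gene_id, mep$gene_id)
    out$mep <- mep$mep[i]
    out$mep_class <- mep$mep_class[i]
  }
  out
}

#' Paired Wilcoxon signed-rank test on expressing fractions
#'
#' Two-sided paired test of R_3 against R_2 across genes (exact for n <= 25
#' without ties, normal approximation with continuity correction otherwise;
#' zero differences are discarded, the standard convention).
#'
#' @param r2,r3 Paired per-gene expressing fractions.
#' @return List: p_value, statistic, n (pairs), n_nonzero (pairs after zero
#'   discard), method.
#' @export
compare_fractions <- function(r2, r3) {
  stopifnot(length(r2) == length(r3))
  if (length(r2) < 6) stop("need at least 6 gene pairs", call. = FALSE)
  d <- r3 - r2
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_, n = length(d),
                n_nonzero = 0L, method = "Wilcoxon signed rank (degenerate)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(r3, r2, paired = TRUE,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), n = length(d),
       n_nonzero = sum(d != 0), method = wt$method)
}

#' Hyperbolic relationship between r_ratio and single-cell fold change
#'
#' Spearman correlation of log(r_ratio) against log(fc_sc) across usable
#' genes, with the model curve `r_ratio = 1.5 / fc_sc` implied by
#' copy-number-proportional expression.
#'
#' @param summary Gene dosage table from [gene_dosage_table()].
#' @param fc_total Total expected fold change (default 1.5 for trisomy).
#' @return List: rho, p_value, n, curve (function of fc_sc).
#' @export
hyperbola_fit <- function(summary, fc_total = 1.5) {
  ok <- summary$usable & is.finite(summary$r_ratio) & is.finite(summary$fc_sc) &
    summary$r_ratio > 0 & summary$fc_sc > 0
  if (sum(ok) < 10) stop("need at least 10 usable genes", call. = FALSE)
  x <- log(summary$fc_sc[ok])
  y <- log(summary$r_ratio[ok])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate (constant) fold changes", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       curve = function(fc_sc) fc_total / fc_sc)
}

#' Dosage decomposition stratified by expression class
#'
#' Per-class medians of r_ratio and fc_sc plus two-sided Mann-Whitney U
#' tests between classes.
#'
#' @param summary Gene dosage table from [gene_dosage_table()].
#' @return List: `medians` (data.frame per class) and `tests` (data.frame of
#'   pairwise Mann-Whitney p-values on r_ratio and fc_sc; empty when fewer
#'   than two classes are populated).
#' @export
stratify_by_expression <- function(summary) {
  s <- summary[summary$usable, , drop = FALSE]
  cls <- c("low", "medium", "high")
  present <- cls[cls %in% s$expression_class]
  med <- do.call(rbind, lapply(present, function(cl) {
    x <- s[s$expression_class == cl, ]
    data.frame(expression_class = cl, n = nrow(x),
               median_r_ratio = stats::median(x$r_ratio),
               median_fc_sc = stats::median(x$fc_sc),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(present) >= 2) {
    pairs <- utils::combn(present, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- s[s$expression_class == pairs[1, k], ]
      b <- s[s$expression_class == pairs[2, k], ]
      data.frame(
        class_a = pairs[1, k], class_b = pairs[2, k],
        n_a = nrow(a), n_b = nrow(b),
        p_r_ratio = suppressWarnings(
          stats::wilcox.test(a$r_ratio, b$r_ratio)$p.value),
        p_fc_sc = suppressWarnings(
          stats::wilcox.test(a$fc_sc, b$fc_sc)$p.value),
        stringsAsFactors = FALSE
      )
    }))
  }
  list(medians = med, tests = tests)
}
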