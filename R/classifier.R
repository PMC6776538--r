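# Iterated 2-means classification of diploid vs trisomic cells in a mosaic
# population. Features per cell: (1) mean min-max-normalised expression of
# supernumerary-chromosome genes, (2) mean ASE at supernumerary sites
# oriented to the current double-allele estimate. Since the double allele is
# unknown at the start, iteration 1 uses the folded magnitude |ASE - 0.5|;
# afterwards the double allele is re-estimated from the cells currently
# labelled trisomic (per site, the allele with the larger summed read count)
# and clustering is repeated until no cell changes label.

#' Per-cell feature matrix for mosaic classification
#'
#' @param expr Genes x cells expression matrix.
#' @param obs Filtered ASE observation table (reference-oriented).
#' @param sites Site annotation table.
#' @param chrom Supernumerary chromosome name.
#' @param double_allele_map Optional named vector site_id -> "ref"/"alt"; when
#'   `NULL` the folded ASE magnitude `|ase - 0.5|` is used (first iteration).
#' @param norm_ref Optional list with per-gene `min` and `max` vectors used to
#'   normalise expression (supply the training values when scoring held-out
#'   cells); default: computed from `expr`.
#' @param cpm Library-normalise expression (counts per million over all genes
#'   of `expr`) before the per-gene min-max step, so that cell-to-cell
#'   library size differences do not masquerade as dosage (default TRUE).
#' @param cell_ids Cells to build features for (default: columns of `expr`).
#' @return A list with `features` (cells x 2 matrix, columns `expr` and
#'   `ase`), `ase_fallback` (logical; cells without usable ASE observations,
#'   whose ASE feature was set to the mean of the observed cells) and
#'   `norm_ref`.
#' @export
build_features <- function(expr, obs, sites, chrom, double_allele_map = NULL,
                           norm_ref = NULL, cpm = TRUE,
                           cell_ids = colnames(expr)) {
  sup_genes <- intersect(unique(sites$gene_id[sites$chrom == chrom]), rownames(expr))
  if (length(sup_genes) == 0) stop("no supernumerary gene with data", call. = FALSE)
  if (length(cell_ids) < 2) stop("need at least 2 cells", call. = FALSE)
  if (cpm) {
    tot <- colSums(expr[, cell_ids, drop = FALSE])
    tot[tot == 0] <- 1
    e <- t(t(expr[sup_genes, cell_ids, drop = FALSE]) / tot) * 1e6
  } else {
    e <- expr[sup_genes, cell_ids, drop = FALSE]
  }
  if (is.null(norm_ref)) {
    norm_ref <- list(min = apply(e, 1, min), max = apply(e, 1, max))
  }
  rng <- norm_ref$max - norm_ref$min
  rng[rng == 0] <- 1  # constant gene: normalised to 0
  en <- (e - norm_ref$min[sup_genes]) / rng[sup_genes]
  en[en < 0] <- 0; en[en > 1] <- 1
  f_expr <- colMeans(en)

  o <- obs[obs$chrom == chrom & obs$cell_id %in% cell_ids, , drop = FALSE]
  if (is.null(double_allele_map)) {
    val <- abs(o$ase - 0.5)
  } else {
    o <- orient_to_double_allele(o, double_allele_map, drop_unknown = TRUE)
    val <- o$ase
  }
  f_ase <- tapply(val, factor(o$cell_id, levels = cell_ids), mean)
  fallback <- is.na(f_ase)
  f_ase[fallback] <- mean(f_ase, na.rm = TRUE)
  if (all(is.na(f_ase))) stop("no supernumerary ASE observation", call. = FALSE)

  features <- cbind(expr = f_expr, ase = as.numeric(f_ase))
  rownames(features) <- cell_ids
  list(features = features, ase_fallback = stats::setNames(as.logical(fallback), cell_ids),
       norm_ref = norm_ref)
}

#' Estimate the double allele of each supernumerary site
#'
#' Per site, the allele with the greater read sum across the cells currently
#' labelled trisomic is taken as the double allele. Ties keep the previous
#' assignment (reference if none); sites with zero reads in trisomic cells
#' keep the previous assignment or stay unknown.
#'
#' @param counts Allele count table.
#' @param sites Site annotation table.
#' @param trisomic_cells Character vector of cell ids currently labelled
#'   trisomic.
#' @param chrom Supernumerary chromosome name.
#' @param previous Optional named vector of previous assignments.
#' @return Named character vector site_id -> "ref"/"alt"/"unknown".
#' @export
estimate_double_allele <- function(counts, sites, trisomic_cells, chrom,
                                   previous = NULL) {
  if (length(trisomic_cells) == 0) {
    stop("no cell currently labelled trisomic", call. = FALSE)
  }
  sup_sites <- sites$site_id[sites$chrom == chrom]
  sub <- counts[counts$site_id %in% sup_sites &
                  counts$cell_id %in% trisomic_cells, , drop = FALSE]
  ref_sum <- tapply(sub$ref_reads, factor(sub$site_id, levels = sup_sites), sum)
  alt_sum <- tapply(sub$alt_reads, factor(sub$site_id, levels = sup_sites), sum)
  ref_sum[is.na(ref_sum)] <- 0
  alt_sum[is.na(alt_sum)] <- 0
  prev <- if (is.null(previous)) {
    stats::setNames(rep("unknown", length(sup_sites)), sup_sites)
  } else previous[sup_sites]
  prev[is.na(prev)] <- "unknown"
  out <- ifelse(ref_sum > alt_sum, "ref",
                ifelse(alt_sum > ref_sum, "alt",
                       ifelse(ref_sum + alt_sum > 0,
                              ifelse(prev %in% c("ref", "alt"), prev, "ref"),
                              prev)))
  stats::setNames(out, sup_sites)
}

# 2-means on z-scored features with deterministic seeded start. Returns the
# kmeans fit (in z-space) plus the scaling and the cluster means of the
# original features; NULL when the features are constant (non-separable).
run_kmeans <- function(features, seed) {
  set.seed(seed)
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  if (sum(scl) < 1e-12) return(NULL)  # all cells identical: non-separable
  scl[scl == 0] <- 1
  z <- scale(features, center = ctr, scale = scl)
  km <- stats::kmeans(z, centers = 2, nstart = 10, iter.max = 50)
  km$feature_center <- ctr
  km$feature_scale <- scl
  km$centers_raw <- rbind(colMeans(features[km$cluster == 1, , drop = FALSE]),
                          colMeans(features[km$cluster == 2, , drop = FALSE]))
  km
}

# cluster -> label mapping: the cluster with the larger centroid sum (higher
# expression + higher DA-oriented ASE) is the trisomic one; invariant to
# cluster id permutation.
trisomic_cluster <- function(km) which.max(rowSums(km$centers))

#' Classify cells of a mosaic population as diploid or trisomic
#'
#' Alternates 2-means clustering of the per-cell (expression, ASE) features
#' with per-site double-allele re-estimation until no label changes (an
#' oscillation of period 2 is also treated as converged). The cluster with
#' the larger centroid sum is called trisomic. A separation guard protects
#' populations without signal (e.g. pure diploid input): when the mean
#' DA-oriented ASE of the candidate trisomic cluster stays below
#' `min_trisomic_ase`, the population is declared non-separable and every
#' cell is labelled diploid.
#'
#' @param counts Allele count table.
#' @param expr Genes x cells expression matrix.
#' @param sites Site annotation table.
#' @param cells Cell table (`cell_id`, `total_mapped_reads`).
#' @param chrom Supernumerary chromosome name.
#' @param max_iter Maximum alternations (default 100).
#' @param seed Integer seed for the k-means starts.
#' @param min_coverage,min_rpsm Observation filters (defaults 16 / 20).
#' @param min_trisomic_ase Separation guard on the trisomic-cluster mean
#'   DA-oriented ASE (default 0.58, midway between the diploid expectation of
#'   0.5 and the trisomic expectation of 2/3).
#' @return A `classifier_state` list: `labels` (named character vector),
#'   `double_allele_map`, `converged`, `separable`, `iterations`,
#'   `label_changes` (per iteration), `features`, `centers`, `norm_ref`.
#' @export
classify_mosaic <- function(counts, expr, sites, cells, chrom,
                            max_iter = 100, seed = 1,
                            min_coverage = 16, min_rpsm = 20,
                            min_trisomic_ase = 0.58) {
  obs <- filter_observations(ase_table(counts, sites, cells),
                             min_coverage, min_rpsm)
  cell_ids <- colnames(expr)
  seeds <- split_seed(seed, paste0("iter", seq_len(max_iter + 1L)))

  ft <- build_features(expr, obs, sites, chrom)
  km <- run_kmeans(ft$features, seeds[[1]])
  non_sep <- function(note) {
    structure(list(
      labels = stats::setNames(rep("diploid", length(cell_ids)), cell_ids),
      double_allele_map = NULL, converged = TRUE, separable = FALSE,
      iterations = 0L, label_changes = integer(), features = ft$features,
      centers = NULL, norm_ref = ft$norm_ref, note = note
    ), class = "classifier_state")
  }
  if (is.null(km)) {
    warning("features are constant across cells; population not separable")
    return(non_sep("constant features"))
  }
  labels <- ifelse(km$cluster == trisomic_cluster(km), "trisomic", "diploid")
  names(labels) <- cell_ids

  da_map <- NULL
  changes <- integer()
  converged <- FALSE
  prev2 <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (!any(labels == "trisomic")) {
      warning("no cell labelled trisomic; population not separable")
      return(non_sep("empty trisomic cluster"))
    }
    da_map <- estimate_double_allele(counts, sites,
                                     names(labels)[labels == "trisomic"],
                                     chrom, previous = da_map)
    ft <- build_features(expr, obs, sites, chrom,
                         double_allele_map = da_map[da_map != "unknown"])
    km <- run_kmeans(ft$features, seeds[[it + 1L]])
    if (is.null(km)) {
      warning("features are constant across cells; population not separable")
      return(non_sep("constant features"))
    }
    new_labels <- ifelse(km$cluster == trisomic_cluster(km), "trisomic", "diploid")
    names(new_labels) <- cell_ids
    changes <- c(changes, sum(new_labels != labels))
    if (all(new_labels == labels)) {
      labels <- new_labels
      converged <- TRUE
      break
    }
    if (!is.null(prev2) && all(new_labels == prev2)) {
      labels <- new_labels  # period-2 oscillation: accept current state
      converged <- TRUE
      break
    }
    prev2 <- labels
    labels <- new_labels
  }
  if (!converged) warning("max_iter reached without label stability")

  ctr <- km$centers_raw[trisomic_cluster(km), ]
  if (ctr[["ase"]] < min_trisomic_ase) {
    warning("trisomic-cluster ASE below separation guard; ",
            "population treated as all-diploid")
    st <- non_sep("separation guard")
    st$converged <- converged
    return(st)
  }
  structure(list(
    labels = labels, double_allele_map = da_map, converged = converged,
    separable = TRUE, iterations = it, label_changes = changes,
    features = ft$features, centers = km$centers,
    centers_raw = km$centers_raw, feature_center = km$feature_center,
    feature_scale = km$feature_scale, norm_ref = ft$norm_ref
  ), class = "classifier_state")
}

#' Assign new cells to a fitted classifier state
#'
#' Builds features for the given cells using the training double-allele map
#' and expression normalisation, then assigns each cell to the nearest
#' k-means centroid (Euclidean distance).
#'
#' @param state A `classifier_state` from [classify_mosaic()].
#' @param counts,expr,sites,cells Data covering the cells to score.
#' @param chrom Supernumerary chromosome name.
#' @param min_coverage,min_rpsm Observation filters.
#' @return Named character vector of predicted labels.
#' @export
predict_mosaic <- function(state, counts, expr, sites, cells, chrom,
                           min_coverage = 16, min_rpsm = 20) {
  if (!isTRUE(state$separable)) {
    return(stats::setNames(rep("diploid", ncol(expr)), colnames(expr)))
  }
  obs <- filter_observations(ase_table(counts, sites, cells),
                             min_coverage, min_rpsm)
  ft <- build_features(expr, obs, sites, chrom,
                       double_allele_map = state$double_allele_map[
                         state$double_allele_map != "unknown"],
                       norm_ref = state$norm_ref)
  z <- scale(ft$features, center = state$feature_center,
             scale = state$feature_scale)
  d <- apply(state$centers, 1, function(ct) {
    colSums((t(z) - ct)^2)
  })
  cl <- max.col(-d)
  tri <- which.max(rowSums(state$centers))
  stats::setNames(ifelse(cl == tri, "trisomic", "diploid"), rownames(ft$features))
}

#' Cross-validated accuracy of the mosaic classifier
#'
#' Stratified k-fold cross-validation against known labels: per fold the
#' classifier is fitted (unsupervised) on the training cells -- including the
#' double-allele estimation -- and applied to the held-out cells.
#'
#' @param counts,expr,sites,cells Simulated or real data.
#' @param truth Named character vector of true labels ("diploid"/"trisomic").
#' @param chrom Supernumerary chromosome name.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (fold assignment and k-means starts).
#' @param ... Passed on to [classify_mosaic()].
#' @return List with `accuracy` (mean held-out accuracy), `fold_accuracy` and
#'   `folds`.
#' @export
cross_validate <- function(counts, expr, sites, cells, truth, chrom,
                           folds = 5, seed = 1, ...) {
  cell_ids <- colnames(expr)
  truth <- truth[cell_ids]
  if (anyNA(truth)) stop("truth labels missing for some cells", call. = FALSE)
  seeds <- split_seed(seed, c("folds", paste0("fit", seq_len(folds))))
  set.seed(seeds[["folds"]])
  fold <- integer(length(cell_ids))
  for (lab in unique(truth)) {
    idx <- which(truth == lab)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  if (any(vapply(seq_len(folds), function(k) {
    length(unique(truth[fold != k])) < 2
  }, logical(1)))) {
    stop("a training fold lacks both classes; use fewer folds", call. = FALSE)
  }
  acc <- vapply(seq_len(folds), function(k) {
    tr <- cell_ids[fold != k]
    te <- cell_ids[fold == k]
    st <- classify_mosaic(counts[counts$cell_id %in% tr, , drop = FALSE],
                          expr[, tr, drop = FALSE], sites,
                          cells[cells$cell_id %in% tr, , drop = FALSE],
                          chrom, seed = seeds[[paste0("fit", k)]], ...)
    pred <- predict_mosaic(st, counts[counts$cell_id %in% te, , drop = FALSE],
                           expr[, te, drop = FALSE], sites,
                           cells[cells$cell_id %in% te, , drop = FALSE], chrom)
    mean(pred[te] == truth[te])
  }, numeric(1))
  list(accuracy = mean(acc), fold_accuracy = acc, folds = folds)
}
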