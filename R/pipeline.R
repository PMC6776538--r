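# End-to-end pipeline: QC -> doublet screen -> (mosaic classification) ->
# ASE tables and MEP -> dosage decomposition. Stage-by-stage record counts
# are logged so every filter is accountable.

#' Pipeline configuration with the analysis defaults
#'
#' All thresholds default to the values the analysis is defined with:
#' coverage >= 16 reads, RPSM >= 20, monoallelic ASE cutoffs 0.1/0.9, MEP
#' classes 0.2/0.8, expression classes 3/15, dosage bands 0.8/1.2, at least
#' 10 expressing cells per usable gene, cell QC at 1e6 mapped reads and 10%
#' expressed genes. The `droplet` preset switches the expressing rule to
#' counts > 5.
#'
#' @param supernumerary_chromosome Triplicated chromosome name.
#' @param mode `"c1"` (full-length, RPSM-based) or `"droplet"` (UMI counts).
#' @param mosaic Run the mosaic classifier (TRUE) or take ploidy labels from
#'   `labels`.
#' @param min_coverage,min_rpsm Observation filters.
#' @param ase_cutoffs,mep_cutoffs,expr_boundaries,dosage_band Thresholds.
#' @param min_expressing_cells Usability rule for dosage genes.
#' @param min_cell_reads,min_expressed_gene_fraction Cell-level QC.
#' @param doublet_band,doublet_min_shared Doublet screen settings.
#' @param escapees Escapee gene ids excluded from X profiles (a plain-text
#'   gene-per-line file or character vector).
#' @param seed Integer seed.
#' @param outdir Output directory (`NULL`: nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(supernumerary_chromosome = "chr21",
                            mode = c("c1", "droplet"),
                            mosaic = TRUE,
                            min_coverage = 16, min_rpsm = 20,
                            ase_cutoffs = c(0.1, 0.9),
                            mep_cutoffs = c(0.2, 0.8),
                            expr_boundaries = c(3, 15),
                            dosage_band = c(0.8, 1.2),
                            min_expressing_cells = 10,
                            min_cell_reads = 1e6,
                            min_expressed_gene_fraction = 0.1,
                            doublet_band = c(0, 0.75),
                            doublet_min_shared = 10,
                            escapees = character(),
                            seed = 1, outdir = NULL) {
  mode <- match.arg(mode)
  if (is.character(escapees) && length(escapees) == 1 && file.exists(escapees)) {
    escapees <- readLines(escapees)
  }
  structure(list(
    supernumerary_chromosome = supernumerary_chromosome, mode = mode,
    mosaic = mosaic, min_coverage = min_coverage, min_rpsm = min_rpsm,
    ase_cutoffs = ase_cutoffs, mep_cutoffs = mep_cutoffs,
    expr_boundaries = expr_boundaries, dosage_band = dosage_band,
    min_expressing_cells = min_expressing_cells,
    min_cell_reads = min_cell_reads,
    min_expressed_gene_fraction = min_expressed_gene_fraction,
    doublet_band = doublet_band, doublet_min_shared = doublet_min_shared,
    escapees = escapees, seed = seed, outdir = outdir
  ), class = "pipeline_config")
}

#' Cell-level quality control
#'
#' Excludes cells with fewer than `min_cell_reads` mapped reads or with fewer
#' than `min_expressed_gene_fraction` of genes expressed. Failing cells are
#' removed, never imputed.
#'
#' @param expr Genes x cells expression matrix.
#' @param cells Cell table with `total_mapped_reads`.
#' @param min_cell_reads,min_expressed_gene_fraction QC thresholds.
#' @return Character vector of passing cell ids.
#' @export
qc_cells <- function(expr, cells, min_cell_reads = 1e6,
                     min_expressed_gene_fraction = 0.1) {
  frac <- colMeans(expr > 0)
  reads <- cells$total_mapped_reads[match(colnames(expr), cells$cell_id)]
  colnames(expr)[reads >= min_cell_reads &
                   frac >= min_expressed_gene_fraction]
}

#' Run the full analysis pipeline
#'
#' @param data An `ase_sim` bundle, or a list with elements `counts`, `expr`,
#'   `sites`, `cells` (as returned by the readers).
#' @param config A [pipeline_config()].
#' @param labels Optional named ploidy labels (used when `config$mosaic` is
#'   FALSE, e.g. genome-matched samples of known ploidy).
#' @return A list: `qc_cells`, `doublets`, `labels`, `classifier`,
#'   `obs_diploid`/`obs_trisomic` (filtered, oriented ASE tables),
#'   `ase_summary` (per ploidy), `mep` (per ploidy), `dosage` (gene table),
#'   `stats` (Wilcoxon on fractions, hyperbola fit, stratification), `log`
#'   (character vector of stage records).
#' @export
run_pipeline <- function(data, config = pipeline_config(), labels = NULL) {
  log <- character()
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log <<- c(log, line)
  }
  chrom <- config$supernumerary_chromosome

  keep <- qc_cells(data$expr, data$cells, config$min_cell_reads,
                   config$min_expressed_gene_fraction)
  say("qc: %d/%d cells pass", length(keep), ncol(data$expr))
  expr <- data$expr[, keep, drop = FALSE]
  counts <- data$counts[data$counts$cell_id %in% keep, , drop = FALSE]
  cells <- data$cells[data$cells$cell_id %in% keep, , drop = FALSE]

  obs_all <- ase_table(counts, data$sites, cells)
  dbl <- NULL
  prof <- x_profiles(obs_all, data$sites, escapees = config$escapees)
  if (nrow(prof) > 0) {
    dbl <- detect_doublets(prof, band = config$doublet_band,
                           min_shared = config$doublet_min_shared)
    flagged <- names(dbl$is_doublet)[dbl$is_doublet]
    say("doublets: %d/%d cells flagged and removed", length(flagged),
        length(dbl$is_doublet))
    keep <- setdiff(keep, flagged)
    expr <- expr[, keep, drop = FALSE]
    counts <- counts[counts$cell_id %in% keep, , drop = FALSE]
    cells <- cells[cells$cell_id %in% keep, , drop = FALSE]
  } else {
    say("doublets: screen skipped (no informative X sites)")
  }

  classifier <- NULL
  if (isTRUE(config$mosaic)) {
    classifier <- classify_mosaic(counts, expr, data$sites, cells, chrom,
                                  seed = config$seed,
                                  min_coverage = config$min_coverage,
                                  min_rpsm = config$min_rpsm)
    labels <- classifier$labels
    say("classify: %d trisomic / %d diploid (converged=%s, %d iterations)",
        sum(labels == "trisomic"), sum(labels == "diploid"),
        classifier$converged, classifier$iterations)
    da_map <- classifier$double_allele_map
  } else {
    if (is.null(labels)) stop("labels required when mosaic = FALSE", call. = FALSE)
    labels <- labels[keep]
    say("classify: skipped, %d labels supplied", length(labels))
    da_map <- estimate_double_allele(counts, data$sites,
                                     names(labels)[labels == "trisomic"], chrom)
  }

  obs <- filter_observations(ase_table(counts, data$sites, cells),
                             config$min_coverage, config$min_rpsm)
  say("ase: %d observations pass coverage >= %d and RPSM >= %g",
      nrow(obs), config$min_coverage, config$min_rpsm)
  dip_cells <- names(labels)[labels == "diploid"]
  tri_cells <- names(labels)[labels == "trisomic"]
  obs_diploid <- obs[obs$cell_id %in% dip_cells, , drop = FALSE]
  obs_trisomic <- obs[obs$cell_id %in% tri_cells & obs$chrom == chrom, , drop = FALSE]
  if (!is.null(da_map)) {
    obs_trisomic <- orient_to_double_allele(obs_trisomic,
                                            da_map[da_map != "unknown"],
                                            drop_unknown = TRUE)
  }
  ase_summary <- list(
    diploid = if (nrow(obs_diploid)) ase_histogram_summary(obs_diploid, config$ase_cutoffs),
    trisomic = if (nrow(obs_trisomic)) ase_histogram_summary(obs_trisomic, config$ase_cutoffs)
  )
  mep <- list(
    diploid = compute_mep(obs_diploid, config$ase_cutoffs, config$mep_cutoffs),
    trisomic = compute_mep(obs_trisomic, config$ase_cutoffs, config$mep_cutoffs)
  )

  dosage <- stats <- NULL
  if (length(dip_cells) && length(tri_cells)) {
    sup_genes <- intersect(
      unique(data$sites$gene_id[data$sites$chrom == chrom]), rownames(expr))
    dosage <- gene_dosage_table(
      expr, labels, genes = sup_genes,
      threshold = if (config$mode == "droplet") 5 else 0,
      min_cells = config$min_expressing_cells,
      expr_boundaries = config$expr_boundaries, mep = mep$trisomic
    )
    say("dosage: %d/%d supernumerary genes usable", sum(dosage$usable),
        nrow(dosage))
    ok <- dosage[dosage$usable, ]
    stats <- list(
      fractions = if (nrow(ok) >= 6) compare_fractions(ok$r2, ok$r3),
      hyperbola = if (nrow(ok) >= 10) hyperbola_fit(dosage),
      strata = if (nrow(ok) > 0) stratify_by_expression(dosage)
    )
  }

  out <- list(qc_cells = keep, doublets = dbl, labels = labels,
              classifier = classifier, obs_diploid = obs_diploid,
              obs_trisomic = obs_trisomic, ase_summary = ase_summary,
              mep = mep, dosage = dosage, stats = stats, log = log,
              config = config)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outdir, f)
    write_tsv(data.frame(cell_id = names(labels), label = labels), p("labels.tsv"))
    if (!is.null(dosage)) write_tsv(dosage, p("gene_dosage.tsv"))
    if (nrow(mep$trisomic)) write_tsv(mep$trisomic, p("mep_trisomic.tsv"))
    if (nrow(mep$diploid)) write_tsv(mep$diploid, p("mep_diploid.tsv"))
    jsonlite::write_json(
      list(ase_summary = ase_summary,
           stats = list(
             fractions_p = if (!is.null(stats$fractions)) stats$fractions$p_value,
             hyperbola_rho = if (!is.null(stats$hyperbola)) stats$hyperbola$rho,
             hyperbola_p = if (!is.null(stats$hyperbola)) stats$hyperbola$p_value
           )),
      p("report.json"), auto_unbox = TRUE, digits = NA, null = "null"
    )
    write_pipeline_config(config, p("resolved_config.yaml"))
    writeLines(log, p("pipeline.log"))
  }
  out
}
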