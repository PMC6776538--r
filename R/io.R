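# Readers and writers. TSV dialect: tab-separated, header row, UTF-8, no
# quoting, missing values as "NA". Coordinates are 1-based inclusive (VCF
# convention) everywhere.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Read heterozygous sites from a VCF or TSV file
#'
#' Biallelic SNVs only: multi-allelic records and indels are skipped with a
#' message; duplicated (chrom, pos) pairs are an error. A TSV file must carry
#' columns `site_id`, `chrom`, `pos`, `ref`, `alt` (and optionally
#' `gene_id`); a VCF contributes CHROM/POS/ID/REF/ALT and gene ids come from
#' `gene_map` (TSV: `site_id`, `gene_id`).
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @param gene_map Optional path to a site-to-gene TSV map.
#' @return Site annotation data.frame: site_id, chrom, pos, ref, alt, gene_id.
#' @export
read_sites <- function(path, gene_map = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    sites <- data.frame(
      site_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
    )
  } else {
    sites <- read_tsv(path)
    need <- c("site_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(sites))) {
      stop("site TSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    sites$pos <- as.integer(sites$pos)
  }
  snv <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1 &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T") &
    !grepl(",", sites$alt, fixed = TRUE)
  if (any(!snv)) {
    message(sum(!snv), " non-SNV or multi-allelic record(s) skipped")
    sites <- sites[snv, , drop = FALSE]
  }
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    stop("duplicated site position(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "),
         call. = FALSE)
  }
  if (any(sites$pos < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  if (!is.null(gene_map)) {
    gm <- read_tsv(gene_map)
    sites$gene_id <- gm$gene_id[match(sites$site_id, gm$site_id)]
  }
  if (is.null(sites$gene_id)) sites$gene_id <- NA_character_
  rownames(sites) <- NULL
  sites
}

#' Write heterozygous sites as a minimal VCF (plus gene map TSV)
#'
#' @param sites Site annotation table.
#' @param path Output VCF path.
#' @param gene_map Optional output path for the site-to-gene TSV map.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, path, gene_map = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mosaicASE",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  ord <- order(sites$chrom, sites$pos)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                  sites$chrom[ord], sites$pos[ord], sites$site_id[ord],
                  sites$ref[ord], sites$alt[ord])
  writeLines(body, con)
  if (!is.null(gene_map)) {
    write_tsv(sites[ord, c("site_id", "gene_id")], gene_map)
  }
  invisible(path)
}

#' Read / write the allele count table
#'
#' TSV with columns `cell_id`, `site_id`, `ref_reads`, `alt_reads`
#' (non-negative integers). When `sites` is given, unknown site ids are an
#' error; when `cells` is given, unknown cell ids are an error.
#'
#' @param path TSV file.
#' @param sites,cells Optional reference tables for validation.
#' @return Allele count data.frame.
#' @export
read_counts <- function(path, sites = NULL, cells = NULL) {
  counts <- read_tsv(path)
  need <- c("cell_id", "site_id", "ref_reads", "alt_reads")
  if (!all(need %in% names(counts))) {
    stop("count TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(counts) == 0) {
    warning("empty allele count table")
    for (col in names(counts)) {
      counts[[col]] <- if (col %in% c("ref_reads", "alt_reads")) integer() else character()
    }
    return(counts)
  }
  for (col in c("ref_reads", "alt_reads")) {
    v <- counts[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop("column ", col, " must contain non-negative integers", call. = FALSE)
    }
    counts[[col]] <- as.integer(v)
  }
  if (!is.null(sites) && !all(counts$site_id %in% sites$site_id)) {
    stop("counts reference unknown site ids", call. = FALSE)
  }
  if (!is.null(cells) && !all(counts$cell_id %in% cells$cell_id)) {
    stop("counts reference unknown cell ids", call. = FALSE)
  }
  counts
}

#' @rdname read_counts
#' @param counts Allele count table to write.
#' @export
write_counts <- function(counts, path) write_tsv(counts, path)

#' Read / write the expression matrix
#'
#' Either a TSV (first column `gene_id`, one column per cell) or a
#' MatrixMarket `.mtx` file with `<path>.rownames` / `<path>.colnames` index
#' files (one id per line).
#'
#' @param path TSV or `.mtx` file.
#' @return Numeric genes x cells matrix.
#' @export
read_expression <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    dimnames(m) <- list(rn, cn)
    return(m)
  }
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (any(is.na(m)) || any(m < 0)) {
    stop("expression matrix must be non-negative and complete", call. = FALSE)
  }
  m
}

#' @rdname read_expression
#' @param expr Expression matrix to write.
#' @export
write_expression <- function(expr, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
    writeLines(rownames(expr), paste0(path, ".rownames"))
    writeLines(colnames(expr), paste0(path, ".colnames"))
    return(invisible(path))
  }
  write_tsv(data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
            path)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round trip is lossless: types are restored on read (thresholds
#' numeric, escapee list character, possibly empty).
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file.
#' @return The configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$escapees <- as.character(unlist(raw$escapees))
  if (is.null(raw$outdir)) raw$outdir <- NULL
  num <- c("min_coverage", "min_rpsm", "ase_cutoffs", "mep_cutoffs",
           "expr_boundaries", "dosage_band", "min_expressing_cells",
           "min_cell_reads", "min_expressed_gene_fraction", "doublet_band",
           "doublet_min_shared", "seed")
  for (k in num) raw[[k]] <- as.numeric(unlist(raw[[k]]))
  structure(raw, class = "pipeline_config")
}

#' Write a simulated population to a directory
#'
#' Writes counts TSV, sites VCF + gene map TSV, expression TSV, cell table
#' TSV, truth TSVs and the configuration as YAML.
#'
#' @param sim An `ase_sim` bundle.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_counts(sim$counts, p("allele_counts.tsv"))
  write_sites_vcf(sim$sites, p("het_sites.vcf"), gene_map = p("gene_map.tsv"))
  write_expression(sim$expr, p("expression.tsv"))
  write_tsv(sim$cells, p("cells.tsv"))
  write_tsv(sim$truth$cells, p("truth_cells.tsv"))
  write_tsv(sim$truth$sites, p("truth_sites.tsv"))
  yaml::write_yaml(unclass(sim$config), p("sim_config.yaml"))
  invisible(dir)
}
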