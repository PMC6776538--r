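# Synthetic single-cell allele-level data under the two-state burst model.
#
# Each allele of a gene is transcribed independently. In the non-overlapping
# burst regime of the telegraph model, steady-state transcript counts per
# allele follow a negative binomial with shape equal to the burst frequency f
# (bursts per mRNA lifetime) and mean f*b, where b is the mean burst size.
# The per-allele zero probability is p0 = (1/(1+b))^f.

#' Burst-model parameters for one gene
#'
#' @param burst_frequency Bursts per mRNA lifetime (f > 0, dimensionless).
#' @param burst_size Mean transcripts per burst (b > 0, dimensionless).
#'
#' @return An object of class `burst_params` with elements `f` and `b`.
#'   The per-allele mean expression is `f * b` and the per-allele zero
#'   probability is `(1/(1+b))^f`.
#' @export
#' @examples
#' bp <- burst_params(0.5, 10)
#' allele_zero_prob(bp)
burst_params <- function(burst_frequency, burst_size) {
  if (!is.numeric(burst_frequency) || length(burst_frequency) != 1L ||
      !is.finite(burst_frequency) || burst_frequency <= 0) {
    stop("`burst_frequency` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(burst_size) || length(burst_size) != 1L ||
      !is.finite(burst_size) || burst_size <= 0) {
    stop("`burst_size` must be a single positive number", call. = FALSE)
  }
  structure(list(f = burst_frequency, b = burst_size), class = "burst_params")
}

#' @rdname burst_params
#' @param params A `burst_params` object.
#' @export
allele_zero_prob <- function(params) {
  stopifnot(inherits(params, "burst_params"))
  (1 / (1 + params$b))^params$f
}

#' Simulate per-allele transcript counts for one gene
#'
#' Draws steady-state transcript counts for `n_alleles` independent alleles of
#' the same gene across `n_cells` cells. Each allele is an independent
#' negative-binomial draw with shape `f` and mean `f * b`, so the expected
#' cell total is `n_alleles * f * b`.
#'
#' @param params A [burst_params()] object.
#' @param n_alleles Number of allele copies (1, 2 or 3).
#' @param n_cells Number of cells.
#' @param seed Optional integer seed.
#'
#' @return Integer matrix of dim `n_cells x n_alleles`; one column per allele.
#' @export
simulate_allele_counts <- function(params, n_alleles, n_cells, seed = NULL) {
  stopifnot(inherits(params, "burst_params"))
  if (!n_alleles %in% 1:3) stop("`n_alleles` must be 1, 2 or 3", call. = FALSE)
  if (!is.numeric(n_cells) || n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(
    stats::rnbinom(n_cells * n_alleles, size = params$f, mu = params$f * params$b),
    nrow = n_cells, ncol = n_alleles
  )
  colnames(m) <- paste0("allele", seq_len(n_alleles))
  m
}

#' Sample sequencing reads at one heterozygous site
#'
#' Models library preparation and sequencing of the transcripts overlapping a
#' heterozygous site. Each transcript is retained independently with
#' probability `capture_efficiency` (allele dropout by Bernoulli thinning; a
#' thinned negative binomial is again negative binomial with mean scaled by
#' the efficiency). Reads are then allocated to alleles multinomially in
#' proportion to the retained transcript counts. The total read count is
#' Poisson: with mean `reads_per_transcript * sum(retained)` when
#' `reads_per_transcript` is given (sequencing depth tracks abundance, the
#' regime of real RNA-seq), otherwise with mean `depth` whenever at least one
#' transcript was retained. Zero retained transcripts always give zero reads.
#'
#' @param allele_transcripts Integer vector (or `n_cells x n_alleles` matrix)
#'   of transcript counts per allele.
#' @param depth Expected total reads at an expressed site (ignored when
#'   `reads_per_transcript` is supplied).
#' @param capture_efficiency Per-transcript retention probability in (0, 1].
#' @param seed Optional integer seed.
#' @param reads_per_transcript Optional expected reads generated per retained
#'   transcript.
#'
#' @return A list with integer matrices `reads` (per-allele read counts) and
#'   `retained` (post-dropout transcript counts), each `n_cells x n_alleles`.
#' @export
simulate_site_reads <- function(allele_transcripts, depth, capture_efficiency,
                                seed = NULL, reads_per_transcript = NULL) {
  if (is.vector(allele_transcripts)) {
    allele_transcripts <- matrix(allele_transcripts, nrow = 1L)
  }
  if (depth < 0) stop("`depth` must be >= 0", call. = FALSE)
  if (capture_efficiency <= 0 || capture_efficiency > 1) {
    stop("`capture_efficiency` must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(allele_transcripts)
  k <- ncol(allele_transcripts)
  retained <- matrix(
    stats::rbinom(n * k, as.vector(allele_transcripts), capture_efficiency),
    nrow = n, ncol = k
  )
  tot <- rowSums(retained)
  if (is.null(reads_per_transcript)) {
    reads_tot <- ifelse(tot > 0, stats::rpois(n, depth), 0L)
  } else {
    reads_tot <- stats::rpois(n, reads_per_transcript * tot)
  }
  reads <- allocate_reads(reads_tot, retained)
  dimnames(reads) <- dimnames(allele_transcripts)
  dimnames(retained) <- dimnames(allele_transcripts)
  list(reads = reads, retained = retained)
}

# Multinomial allocation of read totals across allele columns, vectorised as
# sequential binomials over columns.
allocate_reads <- function(reads_tot, retained) {
  n <- nrow(retained)
  k <- ncol(retained)
  tot <- rowSums(retained)
  reads <- matrix(0L, n, k)
  left <- as.integer(reads_tot)
  rem <- tot
  for (j in seq_len(k)) {
    p <- ifelse(rem > 0, retained[, j] / rem, 0)
    draw <- stats::rbinom(n, left, pmin(pmax(p, 0), 1))
    reads[, j] <- draw
    left <- left - draw
    rem <- rem - retained[, j]
  }
  reads
}

#' Simulation configuration
#'
#' Defaults describe a deep full-length (C1-like) single-cell RNA-seq
#' experiment on an isogenic mosaic population: the same gene panel, with the
#' same per-gene burst parameters, is transcribed from 2 alleles in diploid
#' cells and, on the supernumerary chromosome, from 3 alleles in trisomic
#' cells.
#'
#' @param n_genes Number of autosomal genes (split between the supernumerary
#'   chromosome and a disomic control chromosome).
#' @param n_cells_diploid,n_cells_trisomic Cell numbers per ploidy.
#' @param supernumerary_chromosome Name of the triplicated chromosome.
#' @param control_chromosome Name of the disomic control chromosome.
#' @param frac_supernumerary Fraction of `n_genes` on the supernumerary
#'   chromosome.
#' @param n_genes_x Number of X-linked genes (female sample, one expressed X
#'   haplotype per cell) used by the doublet screen; 0 disables them.
#' @param f_range,b_range Log-uniform sampling ranges for per-gene burst
#'   frequency and burst size.
#' @param mean_site_depth Expected reads at the average expressed site.
#' @param capture_efficiency Per-transcript retention probability in (0, 1].
#' @param library_size Total mapped reads per cell (RPSM denominator).
#' @param doublet_rate Fraction of cells that are doublets, in \[0, 1).
#' @param sites_per_gene Heterozygous sites simulated per gene.
#' @param cell_size_log_sd Log-normal standard deviation of the per-cell size
#'   factor scaling every gene's transcriptional output (0 = identical
#'   cells; the default 0.4 reproduces the 2--3 fold cell-to-cell RNA content
#'   spread of real single-cell libraries).
#' @param rng_seed Integer seed; all randomness flows from it.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       n_cells_diploid = 1000,
                       n_cells_trisomic = 1000,
                       supernumerary_chromosome = "chr21",
                       control_chromosome = "chr1",
                       frac_supernumerary = 0.5,
                       n_genes_x = 100,
                       f_range = c(0.05, 5),
                       b_range = c(2, 50),
                       mean_site_depth = 200,
                       capture_efficiency = 0.05,
                       library_size = 1e6,
                       doublet_rate = 0,
                       sites_per_gene = 1,
                       cell_size_log_sd = 0.4,
                       rng_seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_cells_diploid = n_cells_diploid,
    n_cells_trisomic = n_cells_trisomic,
    supernumerary_chromosome = supernumerary_chromosome,
    control_chromosome = control_chromosome,
    frac_supernumerary = frac_supernumerary, n_genes_x = n_genes_x,
    f_range = f_range, b_range = b_range,
    mean_site_depth = mean_site_depth,
    capture_efficiency = capture_efficiency,
    library_size = library_size, doublet_rate = doublet_rate,
    sites_per_gene = sites_per_gene, cell_size_log_sd = cell_size_log_sd,
    rng_seed = rng_seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genes >= 0, cfg$n_cells_diploid >= 0, cfg$n_cells_trisomic >= 0,
    cfg$n_genes_x >= 0, cfg$sites_per_gene >= 1,
    cfg$frac_supernumerary >= 0, cfg$frac_supernumerary <= 1,
    cfg$cell_size_log_sd >= 0
  )
  if (cfg$capture_efficiency <= 0 || cfg$capture_efficiency > 1) {
    stop("capture_efficiency must be in (0, 1]", call. = FALSE)
  }
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) {
    stop("doublet_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$n_genes + cfg$n_genes_x < 1) stop("empty gene panel", call. = FALSE)
  invisible(cfg)
}

# One master seed -> named integer sub-seeds, one per independent stage.
split_seed <- function(seed, labels) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(labels)), labels)
}

#' Simulate a mosaic single-cell population
#'
#' Generates per-cell per-site allelic read counts, a gene expression matrix
#' (captured transcript counts), heterozygous-site annotations and a ground
#' truth table. Trisomic cells carry 3 allele copies for genes on the
#' supernumerary chromosome (the allele present twice -- the double allele --
#' is drawn uniformly per site and recorded in the truth table) and 2 copies
#' elsewhere. X-linked genes are monoallelically expressed per cell (random
#' X inactivation) with a random per-site haplotype phase.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `ase_sim` with elements `counts` (data.frame:
#'   cell_id, site_id, ref_reads, alt_reads), `expr` (genes x cells matrix of
#'   captured transcript counts), `sites` (site annotations incl. gene map),
#'   `cells` (cell_id, total_mapped_reads), `truth` (list with `cells`:
#'   ploidy and expressed X haplotype per cell; `sites`: double-allele
#'   identity per supernumerary site and haplotype-A allele per X site) and
#'   the resolved `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  validate_sim_config(config)
  seeds <- split_seed(config$rng_seed,
                      c("panel", "transcripts", "capture", "reads", "doublets"))

  set.seed(seeds[["panel"]])
  n_sup <- round(config$n_genes * config$frac_supernumerary)
  chrom <- c(rep(config$supernumerary_chromosome, n_sup),
             rep(config$control_chromosome, config$n_genes - n_sup),
             rep("chrX", config$n_genes_x))
  n_all <- length(chrom)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_all)),
    chrom = chrom,
    f = exp(stats::runif(n_all, log(config$f_range[1]), log(config$f_range[2]))),
    b = exp(stats::runif(n_all, log(config$b_range[1]), log(config$b_range[2]))),
    stringsAsFactors = FALSE
  )

  sites <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(
      site_id = sprintf("%s_s%d", genes$gene_id[i], seq_len(config$sites_per_gene)),
      chrom = genes$chrom[i],
      # chrX gene bodies placed beyond PAR1 (ends at 2,699,520 on GRCh37)
      pos = 3000000L + i * 10000L + seq_len(config$sites_per_gene) * 100L,
      gene_id = genes$gene_id[i],
      stringsAsFactors = FALSE
    )
  }))
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, nrow(sites), replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1L), "")
  # genomic truth, shared by all cells of the (isogenic) individual
  sites$double_allele <- ifelse(
    sites$chrom == config$supernumerary_chromosome,
    sample(c("ref", "alt"), nrow(sites), replace = TRUE), "none"
  )
  sites$hap_a_allele <- ifelse(
    sites$chrom == "chrX",
    sample(c("ref", "alt"), nrow(sites), replace = TRUE), "none"
  )

  n_cells <- config$n_cells_diploid + config$n_cells_trisomic
  cell_id <- sprintf("C%04d", seq_len(n_cells))
  ploidy <- c(rep("diploid", config$n_cells_diploid),
              rep("trisomic", config$n_cells_trisomic))
  x_hap <- sample(c("A", "B"), n_cells, replace = TRUE)
  sdl <- config$cell_size_log_sd
  size_factor <- if (sdl > 0) {
    stats::rlnorm(n_cells, meanlog = -sdl^2 / 2, sdlog = sdl)  # mean 1
  } else rep(1, n_cells)

  # per-gene per-cell retained (captured) transcripts for ref / alt alleles
  set.seed(seeds[["transcripts"]])
  eff <- config$capture_efficiency
  tri <- ploidy == "trisomic"
  ref_t <- alt_t <- matrix(0L, nrow = n_all, ncol = n_cells,
                           dimnames = list(genes$gene_id, cell_id))
  gsite1 <- sites[!duplicated(sites$gene_id), ]  # per-gene genomic truth
  for (i in seq_len(n_all)) {
    f <- genes$f[i]; b <- genes$b[i]
    # copy number per allele and cell (thinned NB: mean scaled by eff)
    if (genes$chrom[i] == "chrX") {
      expr_ref <- (x_hap == "A") == (gsite1$hap_a_allele[i] == "ref")
      draw <- stats::rnbinom(n_cells, size = f, mu = f * b * eff * size_factor)
      ref_t[i, ] <- ifelse(expr_ref, draw, 0L)
      alt_t[i, ] <- ifelse(expr_ref, 0L, draw)
    } else {
      c_ref <- rep(1L, n_cells); c_alt <- rep(1L, n_cells)
      if (genes$chrom[i] == config$supernumerary_chromosome) {
        if (gsite1$double_allele[i] == "ref") c_ref[tri] <- 2L else c_alt[tri] <- 2L
      }
      ref_t[i, ] <- stats::rnbinom(n_cells, size = c_ref * f,
                                   mu = c_ref * f * b * eff * size_factor)
      alt_t[i, ] <- stats::rnbinom(n_cells, size = c_alt * f,
                                   mu = c_alt * f * b * eff * size_factor)
    }
  }
  expr <- ref_t + alt_t

  # site reads: depth proportional to retained abundance, scale set so that
  # the mean over expressed autosomal site-cells equals mean_site_depth
  set.seed(seeds[["reads"]])
  auto <- genes$chrom[match(sites$gene_id, genes$gene_id)] != "chrX"
  mean_ret <- mean(expr[unique(sites$gene_id[auto]), , drop = FALSE][
    expr[unique(sites$gene_id[auto]), , drop = FALSE] > 0])
  if (!is.finite(mean_ret) || mean_ret <= 0) mean_ret <- 1
  rpt <- config$mean_site_depth / mean_ret

  counts <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    g <- sites$gene_id[s]
    ret <- cbind(ref = ref_t[g, ], alt = alt_t[g, ])
    tot <- ret[, 1] + ret[, 2]
    reads_tot <- stats::rpois(n_cells, rpt * tot)
    reads <- allocate_reads(reads_tot, ret)
    keep <- reads_tot > 0
    if (!any(keep)) next
    counts[[s]] <- data.frame(
      cell_id = cell_id[keep], site_id = sites$site_id[s],
      ref_reads = reads[keep, 1], alt_reads = reads[keep, 2],
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL

  sim <- structure(list(
    counts = counts,
    expr = expr,
    sites = sites[, c("site_id", "chrom", "pos", "ref", "alt", "gene_id")],
    cells = data.frame(cell_id = cell_id,
                       total_mapped_reads = rep(config$library_size, n_cells),
                       stringsAsFactors = FALSE),
    truth = list(
      cells = data.frame(cell_id = cell_id, ploidy = ploidy, x_haplotype = x_hap,
                         size_factor = size_factor, stringsAsFactors = FALSE),
      sites = sites[, c("site_id", "chrom", "gene_id", "double_allele", "hap_a_allele")]
    ),
    gene_params = genes,
    config = config
  ), class = "ase_sim")

  if (config$doublet_rate > 0) {
    sim <- inject_doublets(sim, config$doublet_rate, seed = seeds[["doublets"]])
  }
  sim
}

#' Merge random singlet pairs into doublets
#'
#' A doublet is the site-wise sum of two randomly chosen singlets with
#' discordant X haplotypes (the situation the X-correlation screen is built
#' to catch in female samples); the two parents are removed and the merged
#' cell is labelled `doublet` in the truth table.
#'
#' @param sim An `ase_sim` bundle from [simulate_population()].
#' @param rate Fraction of final cells that are doublets, in \[0, 1).
#' @param seed Optional integer seed.
#'
#' @return The modified `ase_sim` bundle.
#' @export
inject_doublets <- function(sim, rate, seed = NULL) {
  stopifnot(inherits(sim, "ase_sim"))
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(sim)
  if (!is.null(seed)) set.seed(seed)

  tc <- sim$truth$cells
  singlets <- tc$cell_id[tc$ploidy != "doublet"]
  # n doublets so that they are `rate` of the final population
  n_final <- round(length(singlets) / (1 + rate))
  n_dbl <- length(singlets) - n_final
  if (n_dbl < 1) return(sim)

  hapA <- tc$cell_id[tc$x_haplotype == "A" & tc$ploidy != "doublet"]
  hapB <- tc$cell_id[tc$x_haplotype == "B" & tc$ploidy != "doublet"]
  n_dbl <- min(n_dbl, length(hapA), length(hapB))
  pa <- sample(hapA, n_dbl)
  pb <- sample(hapB, n_dbl)

  cnt <- sim$counts
  new_rows <- vector("list", n_dbl)
  dbl_ids <- sprintf("DBL%03d", seq_len(n_dbl))
  for (i in seq_len(n_dbl)) {
    sub <- cnt[cnt$cell_id %in% c(pa[i], pb[i]), ]
    agg <- stats::aggregate(cbind(ref_reads, alt_reads) ~ site_id, sub, sum)
    agg$cell_id <- dbl_ids[i]
    new_rows[[i]] <- agg[, c("cell_id", "site_id", "ref_reads", "alt_reads")]
  }
  drop <- c(pa, pb)
  sim$counts <- rbind(cnt[!cnt$cell_id %in% drop, ], do.call(rbind, new_rows))
  rownames(sim$counts) <- NULL

  dbl_expr <- sim$expr[, pa, drop = FALSE] + sim$expr[, pb, drop = FALSE]
  colnames(dbl_expr) <- dbl_ids
  sim$expr <- cbind(sim$expr[, !colnames(sim$expr) %in% drop, drop = FALSE], dbl_expr)

  lib <- sim$cells$total_mapped_reads[match(pa, sim$cells$cell_id)] +
    sim$cells$total_mapped_reads[match(pb, sim$cells$cell_id)]
  sim$cells <- rbind(
    sim$cells[!sim$cells$cell_id %in% drop, ],
    data.frame(cell_id = dbl_ids, total_mapped_reads = lib, stringsAsFactors = FALSE)
  )
  rownames(sim$cells) <- NULL

  sf <- if ("size_factor" %in% names(tc)) {
    tc$size_factor[match(pa, tc$cell_id)] + tc$size_factor[match(pb, tc$cell_id)]
  } else NA_real_
  sim$truth$cells <- rbind(
    tc[!tc$cell_id %in% drop, ],
    data.frame(cell_id = dbl_ids, ploidy = "doublet", x_haplotype = "AB",
               size_factor = sf, stringsAsFactors = FALSE)
  )
  rownames(sim$truth$cells) <- NULL
  sim$truth$doublet_parents <- data.frame(cell_id = dbl_ids, parent_a = pa,
                                          parent_b = pb, stringsAsFactors = FALSE)
  sim
}
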