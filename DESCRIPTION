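Package: mosaicASE
Title: Allele-Specific Expression and Gene Dosage Decomposition in Trisomic
    Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of allele-specific expression (ASE) in
    single-cell RNA-seq of trisomic and diploid cells. Implements a two-state
    burst-like (telegraph) model of independent per-allele transcription with
    negative-binomial steady state, per-site allelic read sampling with
    dropout, ASE computation with coverage and RPSM filters, monoallelic
    expression prevalence (MEP) gene classes, iterative k-means classification
    of diploid versus trisomic cells in mosaic populations with per-site
    double-allele estimation, X-haplotype correlation doublet filtering, and
    the decomposition of gene dosage imbalance into per-cell expression fold
    change and the fraction of expressing cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
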