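---
title: "Allele-specific expression and gene dosage imbalance in trisomic single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific expression and gene dosage imbalance in trisomic single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicASE)
```

## The model

Each allele of a gene is assumed to be transcribed independently by a
two-state (telegraph) promoter. In the non-overlapping-burst regime (gene
inactivation much faster than mRNA decay), steady-state transcript counts per
allele follow a negative binomial with shape equal to the burst frequency $f$
(bursts per mRNA lifetime) and mean $f b$, where $b$ is the mean burst size.
The probability that one allele is silent at the time of sampling is

$$p_0 = \left(\frac{1}{1+b}\right)^{f},$$

so for a gene present in $k$ copies the fraction of cells expressing it is
$R_k = 1 - p_0^k$ and the zero-truncated mean among expressing cells is
$\bar s_k = k f b / R_k$. Because the population mean is copy-number
proportional,

$$\frac{E(s_k)}{E(s_2)} = \frac{R_k\,\bar s_k}{R_2\,\bar s_2} = \frac{k}{2},$$

the familiar 1.5-fold bulk overexpression of a trisomic gene factorises into
two observable components: the ratio of expressing-cell fractions $R_3/R_2$
and the single-cell fold change $\bar s_3/\bar s_2$ among expressing cells,
which trade off along the hyperbola $R_3/R_2 = 1.5/(\bar s_3/\bar s_2)$. For
rarely bursting (low-expressed) genes $p_0 \to 1$ and the imbalance is
carried almost entirely by *more cells expressing* the gene
($R_3/R_2 \to 1.5$); for frequently bursting genes $p_0 \to 0$ and it is
carried by *more transcript per cell* ($\bar s_3/\bar s_2 \to 1.5$).
`fold_changes()` and `gene_dosage_table()` compute both factors per gene; the
identity `fc_bulk = (r3/r2) * fc_sc` is exact bookkeeping on any data and is
asserted to $10^{-9}$ in the tests.

Allele-specific expression (ASE) is, per cell and heterozygous site, the
fraction of reads supporting a designated allele: the reference allele in
diploid regions, and in trisomic regions the *double allele* (the allele
present on two of the three chromosome copies; each supernumerary site has
genotype ABB or BAA). ASE of 0--0.1 is called monoallelic expression of the
alternative/unique allele, 0.9--1 monoallelic expression of the
reference/double allele (both cutoffs inclusive), and the open interval in
between biallelic. Under random, copy-number-proportional allelic selection
the double allele should account for about two thirds of the monoallelic
observations, and the biallelic ASE distribution of trisomic cells should
centre above 0.5, towards $2/3$.

## The synthetic-data generator

`simulate_population()` produces per-cell, per-site allelic read counts with
ground truth, emulating a deep full-length (C1-like) single-cell RNA-seq
experiment on an isogenic mosaic population:

* **Per-allele law.** Independent negative binomials (shape $f$, mean $fb$)
  per allele copy; the double allele of a trisomic site is the sum of two
  such draws, i.e. NB with shape $2f$. A full kinetic simulation of the
  telegraph process is deliberately avoided: the analysis' identities are
  derived in the bursting regime where the NB law is exact.
* **Burst-parameter grid.** Per gene, $f$ is log-uniform on $[0.05, 5]$ and
  $b$ log-uniform on $[2, 50]$, spanning rarely-bursting monoallelic genes to
  high, nearly-biallelic ones.
* **Dropout.** Each transcript is retained with probability
  `capture_efficiency` (Bernoulli thinning, so retained counts stay NB with
  mean scaled by the efficiency — the closed-form oracles survive dropout).
  The default 0.05 reflects the low molecular capture of full-length
  plate/microfluidics protocols and places the simulated monoallelic
  observation fraction near 60%, the regime reported for fibroblasts.
* **Read sampling.** Total reads at a site are Poisson with mean
  proportional to the retained transcript abundance (the proportionality set
  so the mean coverage of expressed site-cells equals `mean_site_depth`,
  default 200), then allocated to alleles multinomially. Coverage *must*
  track abundance: with abundance-independent coverage the 16-read and
  RPSM\ 20 dropout guards would not preferentially remove low-abundance,
  noisy observations, which is their entire purpose.
* **Cell size.** A per-cell log-normal size factor (sdlog 0.4, mean 1)
  scales every gene's output, reproducing the 2--3 fold cell-to-cell RNA
  content spread of real libraries. Set `cell_size_log_sd = 0` for the exact
  iid law (the closed-form oracle tests do).
* **X haplotypes and doublets.** X-linked genes (default 100, a realistic
  count of expressed heterozygous X sites in a female sample) are expressed
  from one randomly inactivated haplotype per cell with random per-site
  phase. `inject_doublets()` replaces pairs of discordant-haplotype singlets
  by their site-wise sum.
* **Determinism.** All randomness derives from `rng_seed` through a fixed
  stream-splitting scheme; identical configurations give bit-identical
  output.

What the generator does **not** emulate: gene length and mappability biases,
UMI chemistry, amplification noise beyond the NB/thinning structure,
correlated bursting between alleles or genes, imprinting, and X-inactivation
escape. Passing tests therefore demonstrate correctness of the *methods*
under the stated stochastic model, not performance on any particular real
data set.

A consequence worth stating plainly: on this compact log-uniform grid, the
aggregated double-to-unique-allele ratio among monoallelic observations
computes to about 2.6 rather than the limit value 2, and the biallelic
trisomic ASE mean to about 0.58 rather than 2/3. Per gene the ratio is
$(1+q)/q \ge 2$ (with $q$ the post-dropout per-allele zero probability),
reaching 2 only as $q \to 1$; the grid's intermediate-$q$ genes keep the
aggregate above it. Real transcriptomes are dominated by very rarely
bursting genes plus a tail of precisely measured, highly expressed ones — a
shape under which both quantities approach their limits, as the package's
low-burst-frequency regression tests (`f` in $[0.05, 0.2]$) confirm.

## Filters and thresholds

| parameter | default | role |
|---|---|---|
| `min_coverage` | 16 reads | minimum site coverage per observation |
| `min_rpsm` | 20 | reads per site per million mapped reads; allele-dropout guard |
| ASE cutoffs | 0.1 / 0.9 (inclusive) | monoallelic vs biallelic calls |
| MEP cutoffs | 0.2 / 0.8 | biallelic / intermediate / monoallelic genes |
| expression classes | 3 / 15 | low / medium / high on the diploid mean (FPKM-scale) |
| dosage bands | 0.8 / 1.2 | insensitive (open interval) / sensitive (> 1.2) |
| `min_expressing_cells` | 10 | gene usability for the dosage decomposition |
| cell QC | 1e6 reads, 10% genes | cells below either are excluded |

Observations with zero coverage are absent, never imputed as 0 or 0.5.
RPSM uses the per-cell total of uniquely mapped reads as denominator. MEP is
evaluated at the gene's most-observed heterozygous site (ties broken to the
lowest genomic position).

## The mosaic classifier

Cells of a mosaic population are classified diploid/trisomic by alternating
2-means clustering with per-site double-allele re-estimation:

1. Features per cell: mean min-max-normalised expression of
   supernumerary-chromosome genes, and mean ASE at supernumerary sites.
   Expression is library-normalised (CPM) before the per-gene min-max step so
   that cell size does not masquerade as dosage; both features are z-scored
   before clustering (k-means is scale-sensitive and the two features have
   arbitrary relative units).
2. The double-allele map does not exist at the start, so iteration 1 uses the
   folded magnitude $|{\rm ASE} - 0.5|$; afterwards each supernumerary site's
   double allele is the allele with the larger read sum across currently
   trisomic-labelled cells (ties keep the previous assignment, else
   reference), and the ASE feature is oriented to it.
3. The cluster with the larger centroid sum is called trisomic; this mapping
   is feature-based and invariant to cluster-id permutation. Convergence is
   no label change; a period-2 oscillation is also accepted (k-means
   alternation can cycle). `max_iter` defaults to 100; in practice 2--4
   iterations suffice.
4. Degenerate input (e.g. a pure diploid population) is caught by a
   separation guard: if the candidate trisomic cluster's mean double-allele
   ASE stays below 0.58 (roughly midway between the diploid expectation 0.5
   and the trisomic expectation 2/3), the population is declared
   non-separable and no cell is forced trisomic. The same rule consequently
   labels a pure *trisomic* population non-separable; the classifier is
   intended for genuinely mosaic samples.
5. Initialisation uses seeded k-means++-style restarts (`nstart = 10`),
   deterministic given the seed. Euclidean distance is assumed throughout.

`cross_validate()` measures held-out accuracy by stratified k-fold: the
classifier (including the double-allele map and feature scaling) is fitted
unsupervised on the training cells and held-out cells are assigned to the
nearest centroid. On a 316-cell 50/50 mosaic at mean site depth 20 and
capture efficiency 0.3, 5-fold accuracy is above 0.95.

## The doublet screen

In female samples each singlet expresses one X haplotype, so per-cell X
allelic-ratio profiles (PAR1/PAR2 and escapee genes excluded) correlate near
+1 within a haplotype group and near −1 across groups. Pairwise Pearson
correlations are computed on at least 10 shared informative sites;
average-linkage hierarchical clustering of the correlation distance
$1 - r$ defines the two haplotype groups. A cell is flagged as a doublet when
its median absolute correlation to *both* groups falls within the exclusion
band, default $[0, 0.75]$. The upper edge separates doublets from the
$|r| \approx 1$ singlet regime; the lower edge is 0 because a doublet with
near-equal parental contributions is correlated with *neither* haplotype
pattern — typical doublets sit around $|r| \approx 0.3$--$0.6$ depending on
how unequal the two cells' RNA contents are. Male or X-homozygous samples
make the screen a documented no-op. Removing flagged cells is pure
filtering: ASE values of the remaining cells are untouched.

## Statistics

Expressing-cell fractions are compared by a two-sided paired Wilcoxon
signed-rank test (exact for $n \le 25$ without ties, normal approximation
with continuity correction otherwise, zeros discarded). The hyperbolic
relationship is assessed by the Spearman correlation of $\log(R_3/R_2)$
against $\log(\bar s_3/\bar s_2)$; expression classes are compared by
two-sided Mann–Whitney U tests. No multiple-testing correction is applied;
raw p-values are reported with test name and $n$. A disomic control
chromosome is simulated alongside the trisomic one and its per-gene ratios
centre at 1 (sign test).

## Problem sizes

The workflow scripts and the acceptance computation use 200 genes with 1000
diploid + 1000 trisomic cells for population-level quantities (a few seconds
of runtime), the 316-cell half-trisomic benchmark for classifier accuracy,
and 300-cell populations with 10% doublets for the doublet screen. The
closed-form oracles are checked on a 5x5 $(f, b)$ grid with 4000 cells per
point.

## Known limitations

* The generator's gene panel is a compact parameter box; see the note above
  on the aggregate monoallelic ratio and biallelic mean.
* The classifier supports whole-chromosome trisomy in mosaic populations
  only: no monosomies, no copy number above 3, no segmental events.
* The doublet screen requires a female, X-heterozygous sample and enough
  shared informative X sites; samples without them are passed through
  unfiltered, with a notice.
* `fc_bulk` is computed from pooled single cells rather than a separate bulk
  library; in an isogenic design the two coincide in expectation.
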