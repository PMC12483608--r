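---
title: "Transcriptional divergence, stem-like states, and chemoresistance analytics"
author: "scDivergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional divergence, stem-like states, and chemoresistance analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scDivergence)
library(SummarizedExperiment)
```

# Scope

scDivergence implements the quantitative core of a single-cell analysis of
treatment-induced transcriptional plasticity in high-grade serous ovarian
cancer (HGSOC): a per-cell transcriptional-divergence statistic, an
unbiased transcription-factor (TF) screen against it, patient-paired
pseudo-bulk comparisons across treatment phases, control-bin gene-module
scoring with one-vs-each cluster enrichment, one-vs-rest and two-group
differential expression with signature intersection,
immunohistochemistry (IHC) h-score quantification, and caliper-based
tumor/spheroid morphometrics. A deterministic synthetic-cohort generator
with planted ground truth makes every stage testable without access to
patient data.

Upstream steps that published tools own — read alignment, SCTransform,
cell-cycle regression, imputation, dimensionality reduction and
clustering, peak calling, motif and GO enrichment — are out of scope;
cluster labels and cell-type annotations are inputs.

# The divergence statistic

For one cell, let $x_{(1)} \ge x_{(2)} \ge \dots \ge x_{(G)} > 0$ be the
sorted expression values of its $G$ detected (non-zero) genes, and
$k = \lfloor G/2 \rfloor$. Transcriptional divergence (the "P50/P50") is

$$ D \;=\; \frac{\sum_{i=1}^{k} x_{(i)}}{\sum_{i=G-k+1}^{G} x_{(i)}} \;\ge\; 1 .$$

A cell that spreads its transcriptional output evenly scores near 1;
a cell that concentrates output in a subset of genes while keeping a long
tail of weakly expressed genes scores high. Divergence is a proxy for
transcriptional malleability: it rises in stem-like and drug-tolerant
states and after cytotoxic stress.

Numerical choices:

* **Odd $G$.** The median value is excluded from both halves, keeping the
  two sums the same size. The original description of the statistic does
  not settle this; exclusion is symmetric and revisitable (it is isolated
  in one place, `transcriptionalDivergence()`).
* **Layer.** Raw counts are the default (the statistic is defined on
  count sums); `layer = "logcounts"` is available. Because the ratio is
  invariant to uniform rescaling of a cell, library-size normalization
  does not change it, and any within-cell monotone transform leaves all
  rank-based downstream tests unchanged.
* **"Top 50% of detected genes"** means the top half *by gene count*,
  not by cumulative expression mass.
* Cells with fewer than two detected genes get `NA` with an explicit
  flag — never a silent 1.

# Rank tests

Group comparisons throughout the package use Wilcoxon tests. The
implementations are exact by enumeration for small samples — all
assignments of the pooled values for the rank-sum test, all $2^n$ sign
patterns for the signed-rank test — which remains valid in the presence
of ties, where the classical exact null distribution does not apply (and
where `stats::wilcox.test()` silently falls back to an approximation).
Beyond the enumeration limit (`choose(n+m, n) > 20000`, or $n > 15$
nonzero pairs) the normal approximation with tie correction and
continuity correction is used; the test suite cross-checks both regimes
against `stats::wilcox.test()` on tie-free data and against brute-force
enumeration oracles elsewhere.

Spearman correlations use average-rank Pearson with the $t$
approximation. Benjamini-Hochberg adjustment validates its inputs and
delegates to `stats::p.adjust`.

# The TF screen and its two FDR families

`tfScreen()` computes, per TF: the Spearman correlation between its
normalized expression (`log1p` CP10k) and per-cell divergence across all
cells, and a rank-sum differential-expression test between the naive and
post-treatment phases with a fold change
$\log_2((\mu_{post}+\varepsilon)/(\mu_{naive}+\varepsilon))$ on the
linear CP10k scale ($\varepsilon = 10^{-9}$, shared with the DE
functions). The correlation p-values and the DE p-values are adjusted as
two *separate* BH families over the tested TFs, and both columns are
reported without privileging either — the corresponding published
screens plot both. TFs detected in fewer than `minCells = 3` cells
(a configurable floor; the source analyses do not state one) are
excluded from both families and from the rank ordering rather than
polluting them with degenerate statistics.

# Module scores and cluster enrichment

`moduleScore()` uses the control-bin construction standard in
single-cell signature scoring: genes are ranked by mean normalized
expression into 24 equal-size bins, each module gene draws 100 control
genes from the non-module genes of its bin (with replacement when the
pool is small), and a cell's score is the mean over module genes minus
the mean over controls. Excluding module genes from their own control
pools keeps the correction from subtracting the signal it should
preserve, and makes the score exactly $\delta$ when every module gene
sits $\delta$ above its bin in some cell. A plain module mean is
available behind `method = "mean"` for sensitivity analysis. Control
sampling is seeded and never perturbs the caller's RNG stream.

`clusterEnrichment()` implements the one-vs-each convention: a feature
is tested between every unordered pair of clusters, all pairwise
p-values form one BH family (per feature), and each cluster is
summarized by its *largest* adjusted value — it is only called enriched
if it beats every other cluster, the conservative reading used to
nominate rare stem-like clusters. Whether the published "highest FDR"
per cluster uses pairwise or repeated one-vs-rest tests is not stated;
pairwise is the default here and `deOneVsRest()` exposes the other
reading (with its own thresholds, FDR < 0.005 and $\log_2$FC > 0, the
convention for cluster marker lists).

One practical note on module inputs: the ovarian cancer stem-cell marker
"SSEA1" is an antigen name, not an HGNC symbol; its gene is *FUT4*. Gene
lists are taken as supplied — map aliases before scoring (the shipped
example list in `inst/extdata/` records the mapping).

# IHC h-scores

Per-cell mean nuclear DAB intensities are pooled across *all* tissues,
cut at the pooled tertiles (nearest-rank quantiles, boundary ties to the
lower bin — no interpolation scheme is stated for the source assay, and
nearest-rank is exact on small samples), and each tissue is scored as

$$ h = 100 \cdot \frac{3\,\mathrm{high}_n + 2\,\mathrm{medium}_n + 1\,\mathrm{low}_n}
{\mathrm{high}_n + \mathrm{medium}_n + \mathrm{low}_n + \mathrm{total}_n}. $$

This formula is applied verbatim. Because every classified cell falls in
exactly one bin, $\mathrm{total}_n$ equals the sum of the three bin
counts, the denominator is twice the cell count, and the score is
compressed to $[50, 150]$ rather than the textbook $[0, 300]$. Whether
that denominator is intentional cannot be determined from its printed
form, so the verbatim variant is the default and
`tissueHScore(classical = TRUE)` provides the textbook score for
comparison. $\mathrm{total}_n$ is taken as the classified-cell count and
recorded per tissue.

# Morphometrics

Tumor volumes from caliper diameters use $V = \pi (d/2)^3$ — again
verbatim, without the $4/3$ sphere factor, since the source convention
prints it that way and percent-change analyses are invariant to the
constant. Spheroid volumes recover an equivalent diameter from the
projected area, $d = 2\sqrt{A/\pi}$ (circular projection; the exact
area/diameter combination used by the source imaging workflow is
unstated), then apply the same volume formula. Percent change is
anchored at a baseline day per animal and flank; zero-baseline series
are excluded with a warning.

# Quality control and normalization

`applyQC()` removes a cell when **any** criterion fails, with strict
inequalities exactly as printed in the multiome convention it follows:
more than $10^5$ or fewer than 1{,}000 RNA (or ATAC) counts, nucleosome
signal $> 2$, TSS enrichment $< 1$, or mitochondrial percentage
$> 50$. Cells sitting exactly on a threshold are kept. RNA-only data are
not penalized: a criterion whose metric is absent is skipped for that
cell and tallied in the QC report. Mitochondrial fraction, when not
supplied, is computed from genes prefixed `MT-` (the human convention).

Normalization is `log1p` CP10k: $v \mapsto \ln(1 + 10^4 v / T)$ for a
cell with total $T$. This stands in for heavier variance-stabilizing
transforms, which are published tools rather than part of this package's
scope; every downstream statistic here is rank-based within cells or
compares the same gene across cells, so results are insensitive to the
choice of within-cell monotone transform. The function refuses
non-integer input — a silent double normalization is the classic failure
mode — and stores both the linear (`cp10k`, used for fold changes) and
log (`logcounts`) layers.

# The synthetic cohort generator

`simulateCohort()` emulates the *structure* the analyses assume, not any
real dataset — the source study gives no distributional statements, so
all generator choices are stand-ins, and the truth manifest says so.

* **Counts**: negative binomial with log-normal gene means
  ($\mu \sim \mathrm{LogNormal}(0, 1)$, size 2), the standard
  overdispersed scRNA-seq emulation.
* **Plasticity**: each cell draws a latent factor
  $f \sim \mathrm{Beta}(2, 4)$. The top half of genes by mean is scaled
  by $1 + (c + s \cdot [\text{post}]) f$ with divergence coupling
  $c = 0.5$ and post-phase shift $s = 0.3$. Scaling the top half
  directly manipulates the P50/P50 numerator, so expected divergence is
  analytically increasing in $f$ and higher post-treatment. The
  phase-independent term $c$ reflects that divergence is a per-cell
  property in both phases; without it the TF screen would see signal
  only through post-phase cells.
* **Planted TF**: one well-expressed gene (upper quartile of means,
  excluded from the top-half scaling so the two mechanisms stay
  separate) has mean $m \cdot e^{3\kappa(f - \bar f)}$ with coupling
  $\kappa = 0.8$ — strictly increasing in $f$, flat when $\kappa = 0$.
  The multiplier is calibrated so the planted signal dominates the
  genuine divergence association that top-half panel TFs inherit
  through $f$.
* **Rare cluster**: a fraction 0.006 of base cells (matching the
  reported 46 of 7{,}273 epithelial cells, ~0.6%), all treatment-naive,
  with the 12 planted module genes scaled 4-fold.
* **Cohort scale**: 11 patients (the longitudinal cohort size) × 2
  phases × 60 cells, 1{,}000 genes, a 50-gene TF panel — large enough
  for stable rank statistics, small enough for multi-seed simulation
  studies.
* **Determinism**: one master seed, expanded into per-stage substreams
  (gene structure, cells, counts, IHC, bulk, QC metrics), so adding a
  stage never perturbs earlier draws and identical configurations are
  bitwise reproducible.

`simulateIHC()` draws Gamma intensities (shape 4, scale 0.25) and shifts
the post-phase mean by exactly `ihcPostShift` through the shape
parameter, giving closed-form means for calibration checks.
`simulateBulkContrasts()` builds two replicate contrasts on the log2
scale sharing planted up/down sets perturbed in the same direction.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: doublets, ambient RNA, batch
and patient-level covariance beyond the phase design, dropout structure
beyond what the negative binomial induces, mean-variance trends,
cell-cycle effects, and any spatial or morphological structure in the
IHC intensities (cells are independent within phase). Recovery rates on
synthetic cohorts demonstrate that the estimators are implemented
correctly and calibrated, not that the biological effects are of any
particular size.

# Calibration study sizes

The acceptance-style checks use: 20 generator-default cohorts for
planted-signal recovery (TF rank, post-phase divergence shift, rare
cluster); 400 reduced cohorts (3 patients × 2 × 25 cells, 300 genes)
for the type-I error of the divergence group test and 200 for the null
TF screen. Null calibrations run on reduced cohorts because the size
properties of rank tests do not depend on cohort scale, and the reduced
cohort keeps a 400-replicate study routine.

# Known limitations

* The signed-rank exact path enumerates $2^n$ patterns; above $n = 15$
  it switches to the tie-corrected normal approximation, which is only
  asymptotically exact.
* `divergenceTable()` assumes the counts layer holds all genes for each
  cell; pre-filtered gene subsets change $G$ and therefore $D$.
* The pseudo-bulk comparison averages the log-normalized layer; with
  very few cells per patient-phase the patient means are noisy and the
  signed-rank test at $n \le 5$ pairs cannot reach $p < 0.05$.
* H-score tertiles are defined on the pooled intensity distribution;
  mixing slides with very different staining batches into one pool will
  encode batch into the bins.
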