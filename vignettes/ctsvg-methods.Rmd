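---
title: "Detecting cell-type-specific spatially variable genes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-type-specific spatially variable genes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsvg)
```

## The problem

Spatially variable genes (SVGs) found across a whole tissue section are
dominated by cell-type marker genes whenever cell types occupy distinct
regions: a gene expressed only in one cell type inherits that type's
spatial footprint and tops every sample-wide SVG ranking, while telling us
nothing that ordinary differential expression between clusters would not.
The scientifically interesting signal is variation of expression with
position *within* a cell type. Detecting it requires (i) single-cell
resolution expression — which on Visium HD means converting 2 µm lattice
squares into per-cell profiles — and (ii) a test that treats the inferred
cell clusters as what they are: estimates with uncertainty, not fixed
labels.

This vignette explains the models and procedures the package implements,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where published descriptions leave latitude.

## From 2 µm squares to cells

**Coordinate convention.** All geometry lives in continuous full-resolution
pixel coordinates, origin at the image top-left, y increasing downward.
Lattice squares are half-open, `[x, x+s) × [y, y+s)`, so the lattice tiles
the plane without double-counting boundary points; the square side in
pixels is `2 / microns_per_pixel`. Points falling exactly on a polygon
edge count as inside, applied consistently everywhere.

**Nucleus filtering.** Segmented nuclei with log area above
`mean(log areas) + 2 sd` are discarded as merged-nucleus artifacts
(natural log, sample sd). When all areas are equal the sd is zero and
nothing is removed; a small relative tolerance (1e-10) on the comparison
absorbs floating-point noise in that degenerate case.

**Square assignment.** Each square's overlap with a nucleus is
approximated by dividing the square into a 10 × 10 lattice of subsquares
and counting subsquare centroids inside the polygon, times the subsquare
area. The square goes to the nucleus with the largest overlap; exact ties
break toward the smallest nucleus id (numerically aware, so "9" precedes
"10"). The approximation errs by at most roughly one subsquare width times
the polygon perimeter; the package carries an independent exact
Sutherland–Hodgman clipping routine (`exact_overlap`) used only for
verification, never by the assignment itself.

**Nucleus expansion.** Whole cells are approximated by scaling each
nucleus contour about its centroid. For a target area ratio $r$ the linear
factor is $\sqrt{r}$, which makes the expanded area exactly $r$ times the
original — the stated area relationship pins down the linear factor, and a
similarity transform is exact in this respect. The default $r = 2$
reflects the empirical whole-cell to nucleus area ratio. A
`linear_ratio = TRUE` compatibility flag instead uses $r$ itself as the
linear factor (area ratio $r^2$) for comparison with implementations that
read the contour formula literally. Squares left unassigned after the
nucleus pass are assigned against the expanded nuclei; the second pass
never reassigns a square claimed in the first.

**Abnormal cells.** A cell is dropped when (a) it owns no squares, (b) its
squares' total area is less than half the cell's area — by default the
expanded-nucleus area, since that approximates the whole cell; a switch
selects the nucleus area instead — or (c) its squares do not form a single
4-connected lattice component. Counts are then summed per cell, and the
cell's coordinate is its nucleus centroid.

## Preprocessing

The aggregated matrix goes through the standard single-cell recipe, via
Seurat: cells expressing at least 300 genes are kept, then genes positive
in at least 1% of retained cells (the fraction compares the raw positive
count to `0.01 n` with `>=`, no rounding); library-size log-normalization
`ln(1 + 10^4 · count/total)`; 2000 highly variable genes (vst); per-gene
scaling clipped at 10; PCA; a shared-nearest-neighbor graph on the top 10
PCs with k = 20; Louvain community detection at resolution 1.2 with an
explicit random seed. The SNN graph is cached in the clustering object so
that community detection can be re-run under different seeds without
recomputing the embedding — the embedding is deterministic, so only the
community detection is seed-sensitive.

## The spatial model

Within one cluster, let $y_{ij}$ be log-normalized expression of gene $i$
in cell $j$ at coordinates $s_j = (s_{j1}, s_{j2})$. Each gene is modeled
as a tensor-product cubic B-spline surface

$$y_{ij} = \beta_{i0}
 + \sum_{k_1} b_{1,k_1}(s_{j1})\,\beta_{i,k_1,0}
 + \sum_{k_2} b_{2,k_2}(s_{j2})\,\beta_{i,0,k_2}
 + \sum_{k_1}\sum_{k_2} b_{1,k_1}(s_{j1})\, b_{2,k_2}(s_{j2})\,\beta_{i,k_1,k_2}
 + \varepsilon_{ij},\qquad \varepsilon_{ij} \sim N(0, \sigma_i^2),$$

with $K$ equidistant internal knots per dimension spanning that cluster's
observed coordinate range and $K+3$ basis functions per dimension — the
standard cubic basis without an intercept column (`splines::bs`), which
keeps the full design of $p = 1 + 2(K+3) + (K+3)^2$ columns at full rank.
(A $K{+}3$-function cubic basis cannot itself sum to one everywhere; the
partition of unity belongs to the $K{+}4$-function basis from which one
column is dropped, and retaining it would make the mains collinear with
the intercept.) The default $K = 2$ gives $p = 36$: few enough columns
that clusters of a few hundred cells stay identifiable, enough for
non-trivial surfaces. Coefficients are estimated by least squares through
one QR factorization of the shared design, so fitting all genes is a
single multi-column solve; the overall regression F statistic
$F_i = \frac{(TSS_i - RSS_i)/(p-1)}{RSS_i/(n-p)}$ is the test statistic,
with $F = 0$ assigned to constant genes. Degenerate geometry that makes
basis columns collinear is handled by dropping dependent columns (pivoted
QR) with a warning and reducing $p$ accordingly.

Before fitting, spatially isolated cells are removed per cluster: the
isolation score is the mean Euclidean distance to the k nearest
within-cluster cells, k being 1% of the cluster rounded half-up and
clamped to [10, 50] (and to $n-1$); cells beyond mean + 6 sd are dropped.
The score uses coordinates only. Genes positive in at least 1% of the
surviving cells form the cluster's tested gene list.

## Significance with clustering uncertainty

Cluster labels are estimates. To propagate their uncertainty, community
detection is re-run with seeds 1..1000 on the cached graph; each original
cluster is matched to its best reassigned cluster per seed by Jaccard
index, and the 100 matches with the highest Jaccard are retained (ties
break toward the smaller seed; `n_seeds` and `keep` scale down together
for desk-sized studies, e.g. 100/20, and the minimum null count drops
from 30 to `keep` accordingly). For each retained match, the isolation
filter is re-applied, the cells' coordinate pairs are permuted uniformly
at random — x and y move together, so the coordinate multiset is invariant
— and the original cluster's gene list is refitted, yielding one null F
per gene per match.

A Gamma distribution is fitted per gene to its null F values (maximum
likelihood, method-of-moments start, via fitdistrplus; zero nulls are
replaced by the smallest positive null × 1e-3; if the fit fails the
empirical permutation p-value $(1 + \#\{null \ge obs\})/(1 + \#nulls)$ is
used). The p-value is the fitted upper tail at the observed F.
Benjamini–Hochberg adjustment is applied within each cluster, FDR ≤ 0.05
is the significance call, and genes are ranked by p then by descending F.
The Gamma is fitted per gene rather than pooled across genes because the
statistic's null scale depends on each gene's expression distribution.

Two properties of this construction are worth stating plainly. First, by
exchangeability the *empirical* permutation p-values are exactly valid;
the Gamma exists to resolve p-values below the $1/(1+\#nulls)$ empirical
floor, and its extrapolated tail is slightly lighter than the permutation
distribution's when the residual degrees of freedom $n - p$ are only a few
hundred — the approximation converges as clusters grow into the thousands
of cells typical of Visium HD, since $F(p-1, n-p) \to$ Gamma as
$n \to \infty$. Second, when clustering is genuinely uncertain the
reassigned clusters differ from the original, widening the null and making
the test conservative — that is the intended behavior, and it is why the
permutation test controls false positives in the sample-wide-null study
where the parametric $F(p-1, n-p)$ baseline (also provided, as
`parametric_pvalue_baseline`) over-rejects on sparse log-normalized
counts.

## Downstream analysis

Significant genes per cluster are standardized (fitted values to mean 0,
sample sd 1; constant surfaces to zero with a warning) and grouped by
k-means over k = 1..15 with 25 restarts under a fixed seed. The module
count is chosen at the elbow of the within-to-total sum-of-squares curve:
the k with maximum perpendicular distance to the chord joining the curve's
endpoints, after rescaling both axes to [0, 1] so the rule is unit-free.
Each module's metagene is the unweighted per-cell mean of its members'
standardized surfaces.

Cluster markers come from a per-gene Wilcoxon rank-sum test of each
cluster against all other cells (normal approximation with tie and
continuity correction — matching `wilcox.test(exact = FALSE)`), after
seeded downsampling to at most 5000 cells per cluster; the top 50 genes by
p (ties broken by descending absolute log fold change) per cluster and
their union define the marker set against which SVG novelty
(`svg_marker_overlap`) is measured. Gene-set enrichment of modules is a
one-sided hypergeometric test against user-supplied GMT sets restricted to
the tested universe, BH-adjusted, retained at FDR ≤ 0.05 and ordered by
observed/expected fold change.

## Benchmarking assignment

The evaluation harness mimics the imaging-platform benchmark: transcripts
with gold-standard cell labels (point-in-whole-cell-polygon), nucleus
polygons, and whole-cell polygons. The nucleus pipeline is run on
transcripts binned to the 2 µm lattice; the baseline pools the lattice
into 8 µm squares and assigns each *cell* to its largest-overlap square
(same subsquare approximation), so one square may serve several cells —
those cells then share (double-count) the square's transcripts, except in
the transcript-mapping-accuracy metric, where each shared square is first
given to one of its cells uniformly at random under a seed to make the map
single-valued. Accuracy is the fraction of transcripts whose predicted and
gold assignments agree (same cell, or both unassigned). Expression
agreement takes cells with ≥ 10 total reads, log-normalizes with scale
factor 100, scales per gene, computes each cell's Pearson correlation
across genes against the gold profile, and reports the median
(zero-variance cells are excluded with a warning). Clustering agreement is
the adjusted Rand index between cluster labels derived identically from
each matrix.

## The synthetic-data generator

`generate_tissue` places elliptical nuclei (log-normal areas, default
meanlog log(600) px², sdlog 0.25, i.e. ~37 µm² at 0.25 µm/px — a typical
nucleus — and whole cells twice that) by rejection sampling so expanded
cells are pairwise disjoint; cell types follow Gaussian spatial blobs;
per-cell transcript counts are Poisson with per-type gene rates (default
panel: 10 markers per type at rate 8 vs 0.4, 20 shared genes at rate 2),
optionally modulated by a smooth field — linear gradient or radial bump —
evaluated at the cell centroid; transcript positions are uniform inside
the whole-cell polygon, plus a uniform background. Everything is a pure
function of the spec and its seed. `generate_ideal_tissue` builds the
degenerate best case: square cells aligned to the lattice with one-square
gaps, nuclei being cells shrunk by $1/\sqrt{2}$, so the expanded nucleus
reproduces the cell exactly and a correct implementation maps every
transcript to its cell. `generate_null` permutes coordinate pairs
sample-wide; `generate_svg_expression` and `generate_type_expression` /
`generate_type_counts` plant spatial fields and cell-type structure in
expression space directly.

What the generator does **not** emulate: segmentation errors and doublets,
subcellular transcript localization, H&E image content, spatial
autocorrelation of library size, and overlapping nuclei. Passing tests on
these tissues therefore demonstrate correctness of the geometry,
aggregation, and inference machinery under the stated models — not
robustness to segmentation noise in real images.

## Validation study sizes

The packaged checks run at deliberately modest sizes chosen to exercise
the statistics without excess compute: the geometry oracle uses 500 random
square/ellipse pairs; the batch-fit oracle 20 genes × 300 cells; the
F-null check 2000 genes at $n = 300$, $p = 36$; the sample-wide-null
calibration study 600 cells × 500 sparse-count genes with re-clustering at
100 seeds keeping 20 matches; the planted-SVG recovery study two ~1000-cell
clusters × 240 genes (60 planted at effect/noise 3, i.e. a 25% planted
fraction, with 100 seeds/100 matches — cluster sizes in the thousands are
the platform's operating regime and where the Gamma tail approximation is
accurate); and the assignment benchmark five 60-cell tissues plus the
ideal lattice tissue. The recovery study's moderate type separation
(marker shift 1 sd) keeps clustering realistic rather than trivially
stable.

## Known limitations

- Square assignment is hard (one cell per square); no fractional
  splitting.
- The Gamma tail is an extrapolation below the empirical permutation
  resolution; with small clusters (residual df of a few hundred) its
  smallest p-values run mildly anti-conservative, which can lift the
  realized false-discovery proportion a few points above the nominal level
  when many strong discoveries widen the BH threshold. Interpret
  borderline calls near the cutoff accordingly, or enlarge `keep`.
- HDF5 feature-barcode input is not supported; convert to MatrixMarket.
- Expansion assumes star-shaped-about-centroid nuclei; extremely concave
  contours may expand onto neighboring tissue.
- The isolation filter is purely spatial and assumes roughly convex
  cluster footprints.
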