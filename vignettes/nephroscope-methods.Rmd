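---
title: "nephroscope: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nephroscope: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models
each stage assumes, the thresholds and their defaults, what the
synthetic-data generators emulate (and deliberately do not), and the
design decisions taken where more than one reasonable choice existed.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Cell quality control

Droplet scRNA-seq of fetal kidney is dominated by two artifacts:
dissociation stress (the kidney is hard to dissociate, and prolonged
enzymatic incubation induces immediate-early and heat-shock programs)
and red-blood-cell contamination. `compute_cell_qc()` reports, per
cell, the UMI total and the fractions of expression from the
mitochondrial (13 protein-coding MT genes), stress-marker, and
hemoglobin (*HBB*, *HBA1*, *HBA2*) lists. Fractions always use the
cell's full unfiltered total as denominator, so they do not depend on
any upstream gene exclusion; a zero-total cell has all fractions
defined as 0 and falls into the low-count class.

`filter_cells()` applies the removal rules with **strict** inequalities
— a cell is removed when its total is *below* 2,000 UMI, or a fraction
is *above* 10% (mitochondrial), 5% (stress), or 1% (hemoglobin) — and a
fixed precedence: low count, then stressed, then red blood cell. The
depth filter is applied first because a low-count cell's fractions are
too noisy to interpret; the mitochondrial/stress rule is a logical OR;
each cell receives exactly one flag so the four classes partition the
input exactly (asserted on every run of the test suite). Whether
stress fractions are computed before or after the depth filter cannot
change any fraction (denominators are per-cell), only the bookkeeping
of class sizes, which the precedence order makes explicit.

## Count smoothing

`knn_smooth()` reduces technical noise by summing the raw profiles of
each cell and its `k = 10` nearest neighbors — cells transcriptionally
similar enough that they likely share a type. Neighbors are found by
Euclidean distance in the first `n_pcs = 10` principal components of
median-normalized, square-root-stabilized counts. A seeded uniform
jitter with total amplitude `dither = 0.05` times each component's
range is added to the coordinates **only** for the neighbor search; the
summed profiles are untouched. The exact dither semantics of the
published smoothing tool are not printed anywhere we could verify, so
the uniform-jitter reading is recorded here as an assumption. The
smoothing runs in one pass at the final `k` rather than the published
stepwise doubling; at `k = 10` the two differ only in which of several
near-equivalent neighbor sets is summed, and the one-pass variant is
directly testable (two identical cells with `k = 1` must reproduce
their common profile exactly). The summed matrix is rescaled by one
global factor so its grand total equals the input's — conservation the
tests assert to machine precision.

Smoothing trades variance for a local bias: profiles of neighboring
cells bleed into each other, which inflates detection fractions and
blurs boundaries between very similar types. Downstream defaults
(detection thresholds, marker criteria) are calibrated on smoothed
matrices, matching the pipeline's intended order.

## Normalization and transformation

Size factors come from the pool-and-deconvolve estimator
(`scran::calculateSumFactors` behind `estimate_size_factors()`):
overlapping pools of cells (default sizes 21, 41, 61, clipped to the
cell count) are summed, compared with the average profile, and the
per-cell factors recovered by least squares — robust to the zeros that
defeat per-cell ratio estimators. With fewer cells than the smallest
pool the system is under-determined and the function falls back to
library-size factors with a message; a non-positive solved factor is an
error rather than something to silently clamp. Factors are rescaled to
mean 1, and on exactly depth-scaled profiles the estimator reproduces
the library-size oracle to numerical precision (asserted in the
tests).

Normalized values are variance-stabilized with the classical
Freeman-Tukey transform `FT(x) = sqrt(x) + sqrt(x + 1)`; `FT(0) = 1`,
which the detection logic uses: on an FT-tagged matrix "detected" means
`value > 1`, exactly equivalent to a nonzero count.

## Highly variable genes

`select_hvg()` ranks genes by `CV² / trend(mean)` where the technical
trend `CV²(μ) = a + b/μ` — the classical technical-noise model in which
Poisson sampling contributes the `b/μ` term — is fitted by iteratively
bisquare-reweighted least squares (20 iterations, residual scale by
MAD; the fit is floored at 1e-8 before division). This is a
contract-level stand-in for reference implementations of the same idea,
not a port of any of them. The top `fraction = 0.05` of the
non-excluded expressed genes are selected; stress-marker and ribosomal
lists are excluded *before* ranking, so an excluded gene can never be
selected regardless of its CV². `min_mean` (default 0, i.e. no filter)
reproduces both published usages — no minimum for the main maps, 0.01
for display heatmaps.

## Clustering and merging

Cells are clustered with Ward linkage (`hclust`, `ward.D2`) on
`d = 1 − r` Pearson correlation distances over the selected HVGs;
`correlation_distance()` refuses zero-variance cells by name rather
than emitting NaNs. Because Ward heights on correlation distances are
dataset-specific, the recommended cutting interface is `n_clusters`; a
raw `height` cut is also available. Labels are renumbered by cluster
size, so label 1 is always the largest cluster.

Merging over-cut clusters is first-class: an explicit merge map (the
auditable record of manual decisions) is applied verbatim, and an
automatic mode iteratively merges the pair of clusters whose mean
literature-marker profiles correlate above `auto_threshold`, highest
correlation first, size-weighting the merged profile. The auto rule
deliberately considers **all** current pairs rather than only
dendrogram siblings: profile similarity, not tree adjacency, is the
scientific criterion, and restricting to siblings would forbid exactly
the kind of non-adjacent merge that marker evidence can justify.

Cluster expression summaries (`cluster_profile()`) average Freeman-
Tukey values per cluster and Z-standardize each gene across clusters;
genes constant across clusters are flagged and standardized to zero
instead of NaN.

## AUROC marker selection

For each gene the cluster of interest (COI) is the cluster with the
highest mean expression. A binary classifier that calls a cell "COI"
when the gene's expression exceeds a threshold traces an ROC curve as
the threshold sweeps; `gene_auroc()` computes its area by the rank
(Mann-Whitney) formula with midranks, which is identical to the
explicit sweep — the test suite checks this equality exactly on 200
random tie-heavy instances. Rank-based AUROC is invariant to monotone
transforms, so it does not matter whether it is computed on normalized
or FT values; the mean-expression criterion, whose 1.5 threshold is
scale-dependent, is defined on the FT scale used throughout.

A gene is a candidate iff all four criteria hold, with boundary
strictness following their wording: AUROC strictly *exceeding* 0.8;
detection in *at least* 80% of COI cells; COI mean *at least* 1.5; the
fraction of non-COI cells expressing above the COI's 25th percentile
*at most* 25%. "Cells outside the COI" are pooled across all other
clusters (the plain reading; a per-cluster variant would make the
criterion harder as cluster numbers grow). Candidates are ranked per
cluster by AUROC with a deterministic tie-break (detection fraction,
then COI mean, then gene name — the published procedure does not
specify one) and the top `top_k = 4` are selected. Every selected
record keeps its four pass flags so the selection can be audited
independently.

## Identity-score classification

`train_id_classifier()` fits an L1-penalized multinomial logistic
regression (glmnet) on the 500 most variable genes, shrinkage chosen by
20-fold cross-validated deviance (folds are reduced with a warning when
a class is smaller than the fold count). The genes with any nonzero
weight form the classifier set. `predict_id_scores()` returns softmax
probabilities; a cell's identity score is its maximal class
probability, and missing model genes in a test matrix are imputed as
zero with a warning rather than failing.

## Batch integration and label transfer

`mnn_correct()` works in a common PC basis (50 components in the
standard workflow) and merges batches by decreasing size. For each
query batch it finds mutual k-nearest-neighbor pairs (k = 20) against
the growing reference. The correction is two-stage:

1. the **constant** component — a translation, the dominant term of a
   batch effect — is the mean of all pair difference vectors, iterated
   until the shift stalls (at most 20 iterations, stop at 1e-3 of the
   first shift). One pass provably under-corrects a large offset
   because mutual pairs form between the facing edges of the two
   clouds; iterating the global mean removes that bias, whereas
   iterating a *local* kernel average converges to a biased fixed point
   in which every query settles at the local mean of its pair partners.
2. one **local** pass then shifts each cell by a Gaussian-kernel
   weighted average of pair corrections (bandwidth `sigma`, default 0.1
   times the RMS pairwise distance of the reference), capturing
   position-dependent distortion. Kernel weights are measured to the
   pair *midpoint*: between two identical clouds the mutual-pair
   relation is symmetric, opposite pair vectors share a midpoint and
   cancel exactly, so identical batches are not moved at all — an
   invariant the tests assert.

This is a deliberately simplified scheme sharing the mutual-pair
contract of the full published MNN algorithm; it does not
cosine-normalize, project out the batch subspace, or adjust variance.
Reference coordinates are never modified. `knn_classify()` transfers
labels by majority vote over the 20 nearest labeled cells, ties broken
by the smallest mean distance among tied classes, and is invariant to
reference ordering.

## Differential expression

`differential_expression()` models raw (never smoothed) counts with
per-gene negative binomial GLMs whose design contains the group factor
and the **centered cellular detection rate** — each cell's fraction of
detected genes. The published description ("a detection rate for each
gene was added to the design matrix") is ambiguous between a per-cell
covariate and a per-gene quantity; only the per-cell reading yields a
valid design column, so that is implemented, and the per-gene per-group
detection fractions are reported descriptively in the result. The
backend is edgeR (TMM normalization, trended dispersion); the default
test is the likelihood-ratio test on the trend-shrunk fits — the
simplest member of the model family to verify against simulation — and
the quasi-likelihood F-test is available via `test = "qlf"`. The test
suite checks calibration at the null (type-I error within [0.03, 0.07]
at nominal 0.05; Kolmogorov-Smirnov distance of the null p-values below
0.05) and power ≥ 0.8 for planted 4-fold genes at FDR < 0.05 with 100
cells per group. `fold_change_filter()` applies strict
`|L2FC| > log2(min_fold)` and `FDR < max_fdr`, with "any comparison"
semantics across pairwise contrasts.

## Pseudotime

`learn_tree()` replaces reversed-graph-embedding trajectory learners
with a transparent stand-in that keeps their contract: seeded k-means
centroids (default `max(10, n/100)` nodes, 10 restarts) joined by a
Euclidean minimum spanning tree, every cell projected to the nearest
point on any edge. Spanning-tree structure (connected, acyclic) is
asserted on every run. `compute_pseudotime()` roots the tree at a node
or at the node nearest a named cluster's centroid — mirroring the
practice of rooting at the earliest progenitor state, the pretubular
aggregate — and defines pseudotime as geodesic arc length from the root
to each projection; branches are maximal tree segments between nodes of
degree ≥ 3. Because the stand-in is not the published algorithm,
trajectory figures are reproduced in spirit, not numerically; the tests
require Spearman ≥ 0.9 against planted latent time on a linear
trajectory and a single detected branch point on a planted Y in ≥ 90%
of tree seeds. The branch geometry of a Y lives in 2–3 dimensions, so
the workflow embeds smoothed, FT-transformed counts in 3 components for
trajectory work; higher-dimensional embeddings admit spurious
minimum-spanning-tree side branches driven by noise directions.

## Enrichment

`fisher_enrichment()` computes the one-sided (greater) Fisher p-value
as the hypergeometric upper tail of the 2×2 overlap table, with the
odds ratio flagged `Inf` when a margin cell is empty. The gene universe
is a parameter — the convention here is all genes detected in the
expression matrix — because the published analysis does not state its
universe and enrichment p-values are meaningless without one. The
trait lists themselves are inputs (GWAS catalogs drift between
versions; retrieval is out of scope). `bh_adjust()` validates inputs
and delegates to the standard step-up implementation.

## Image quantification

All geometry is 0-based pixel-center `(row, col)`; micrometers appear
only at reporting via `pixel_size`.

**Background.** `rolling_ball_subtract()` estimates background as the
grayscale morphological opening with a disk (radius 3 px for smFISH,
100 px for immunostaining) — the standard surrogate for a rolling
ball — and clips the difference at zero. EBImage's grayscale morphology
operates on [0, 1], so the image is rescaled around the opening.
**Autofluorescence** is removed by regressing each channel on the GFP
channel through the origin over ROI background pixels (below the
channel's spot threshold) and subtracting the scaled GFP image; an
all-zero GFP channel degrades to the identity with a warning.

**Spot calling.** `detect_spots()` binarizes within the ROI at a global
threshold, labels 8-connected components, and keeps components with
mean intensity strictly above the third quartile of all ROI pixel
intensities (the "all ROI pixels" reading of an ambiguous rule,
recorded here) and area ≥ 3 px; density is count over ROI area. The
default threshold is the **triangle** (Zack) method on the ROI
histogram — spots occupy well under 1% of pixels, so the histogram is
unimodal with a long tail, the regime the triangle method is built for,
whereas Otsu assumes two balanced classes and collapses into the noise
band on such images (measured during development: an Otsu threshold
inside a unit-noise band, precision 0.13 on a 10× SNR fixture). The
triangle histogram drops the clip-at-zero spike left by background
subtraction and is 5-bin smoothed before peak finding; Otsu and
absolute thresholds remain available, and a constant ROI is an error
directing the user to an absolute threshold. Group densities are
compared pairwise by two-sided Mann-Whitney tests with BH adjustment
(the published figure does not name its test; Mann-Whitney is the
conservative default for small-n densities), starred at adjusted
p < 0.05 and < 0.0005.

**Niche profiles.** `quantify_niche_profiles()` expresses intensity in
the niche coordinate system: distance `d` from the ureteric-bud contour
and relative arc-length position `s ∈ [0, 1]` along it. Cross-sections
are reproducible contour normals every 30 px of arc length (hand-drawn
polylines are still accepted; the side of the contour is chosen by ROI
coverage or forced via `normal_side`); intensity is sampled at 1-px
steps along each section and averaged over a perpendicular 30-px line
(bilinear interpolation, out-of-image samples dropped). Averaging the
per-section profiles over `s` gives the d-profile with SEM over
sections; averaging over `d` gives the s-profile. Each channel's
profile is max-normalized, and the first/second channel ratio is
reported for both raw and normalized profiles — identical channels give
a ratio identically 1.

## Synthetic data: what is and is not emulated

The generators define the study conditions under which every claim is
tested; their defaults are fixed, not tuned per test.

`generate_counts()` draws independent negative binomial counts with
`variance = μ + φμ²` (φ = `dispersion`, default 0.1; φ = 0 gives
Poisson). Defaults: 8 clusters × 150 cells, 2,000 genes with
log-normal baseline means (sdlog 0.7) averaging 1.5 UMI — an expected
~3,000 UMI per cell, comfortably above the 2,000-UMI filter — five
exclusive 8-fold markers per cluster, background contamination
fractions of 3% / 1.5% / 0.1% (mitochondrial / stress / hemoglobin),
and designated subsets (5% stressed, 1% red-blood, 2% low-depth cells)
planted at twice the QC thresholds (20% mitochondrial and 10% stress;
2% hemoglobin; 0.3× depth). Contamination counts in designated cells
are drawn Poisson rather than negative binomial: the contaminating
material is technical, and with only three hemoglobin genes NB noise at
φ = 0.1 would miss the 1% threshold in roughly 1% of planted cells,
which would misrepresent a subset that is planted *by construction* to
exceed it. Batch effects are gene-wise log-normal multipliers
`exp(strength · z_g)` with a shared standard-normal loading. Not
emulated: ambient RNA, doublets, gene-gene correlation beyond cluster
structure, UMI saturation. Passing tests therefore demonstrate
correctness of the machinery under the stated model, not robustness to
artifacts the model omits.

`generate_trajectory_counts()` builds piecewise-linear gene means along
a rooted segment tree (parents must precede children, which excludes
cycles): per-segment gene sets ramp 8-fold along their segment and stay
high in descendants, and a set of "time genes" grows monotonically with
depth. Latent time (segment depth + within-segment position) is
recorded per cell.

`generate_spot_image()` composes constant background, an optional
autofluorescence template, Gaussian spots, and i.i.d. Gaussian noise,
recording true centers. Spot centers honor a minimum separation of
6 × `spot_sigma` by rejection sampling: two Gaussian spots separated by
`s` have a saddle at `2·exp(−(s/2σ)²/2)` of peak height, so a component
caller with a half-peak global threshold can only resolve pairs beyond
≈ 4.7σ — the generator plants spots that are countable at all, because
coincident single molecules are not, by any component-based method.
`generate_gradient_image()` adds `amplitude · exp(−d/λ)` around a
contour polyline, the planted analog of a signaling gradient around the
ureteric bud. Images are 2-D only (stacks are max-projected upstream in
the published workflow); no PSF or 3-D deconvolution is modeled.

## Numerical conventions and degenerate inputs

- PCA signs are fixed by making each loading's largest-magnitude entry
  positive, so repeated runs are bit-identical; empty gene subsets are
  errors.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state.
- Correlation distances are clipped into [0, 2] against rounding; a
  zero-variance cell is an error naming the cell.
- `cut_dendrogram()` requires exactly one of height / cluster count;
  empty clusters in profile computation are errors, zero-sd genes are
  flagged, not NaN.
- MTX interchange uses genes-as-rows with 1-based indices on disk;
  symbols are matched case-insensitively and stored uppercase; registry
  symbols missing from a matrix warn rather than fail.
- The marker top-4 tie-break and the kNN-transfer tie-break are
  deterministic and documented above.

## Known limitations

- The trajectory, MNN, and CV²-trend components are documented
  stand-ins sharing their originals' contracts, not their internals;
  quantities that depend on those internals (exact embeddings, exact
  cluster counts at a fixed dendrogram height) are not reproduced.
- Cell-cycle scoring by a trained classifier is out of scope; the
  proliferation-marker Z-score (`proliferation_score()`) is the
  supported proliferation readout.
- The stress-marker list shipped in `default_gene_lists()` is a compact
  representative immediate-early/heat-shock set suitable for synthetic
  data; real analyses should load the full curated list via
  `read_gene_lists()`.
- Problem sizes in the tests (up to ~3,300 cells × 2,500 genes for the
  full-pipeline checks, chosen as comfortable desk-scale analyses) use
  dense distance matrices; beyond ~10⁴ cells the quadratic memory of
  `dist()` becomes the binding constraint and an approximate-neighbor
  backend would be the natural extension.
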