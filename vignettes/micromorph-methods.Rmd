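---
title: "Methods: joint morphology and subcellular transcript analysis of microglia"
author: "micromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint morphology and subcellular transcript analysis of microglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

micromorph analyses imaging-based spatial transcriptomics of microglia in
which every decoded mRNA molecule carries a gene label and a 3D position
(x, y in pixels; z as a plane index), alongside multi-channel
immunofluorescence stacks (a microglial stain, a nuclear stain, and an
astrocyte stain). The pipeline answers three linked questions:

1. **Where is each molecule within its cell?** Cells are segmented from the
   microglial stain, matched one-to-one to transcriptomically derived
   boundary polygons, and decomposed into a *soma* (nucleus-overlapping)
   and a *process* (branched projection) compartment; molecules are
   assigned per z-plane.
2. **How is morphology quantified?** A 26-feature morphometric vector,
   skeleton and Sholl analysis, box-counting fractal dimension and
   gliding-box lacunarity, a 512-dimensional image embedding, and
   elbow-selected k-means classes ordered from amoeboid (C1) to ramified
   (Ck).
3. **How do the two interact?** Mann-Whitney differential expression
   between compartments, Spearman morphology-gene correlation with strict
   train/test separation, a random-forest ramification classifier, and
   compartment-constrained spatial statistics: a 3D Ripley K/H clustering
   test with Monte-Carlo envelopes and a permutation-null gene-gene
   co-localization network.

Because the real tissue data cannot ship with the package, a first-class
synthetic generator plants known ground truth — shape class, per-gene
compartment log-odds, Thomas-process clustering, shared-parent
co-localized pairs, astrocyte contamination, and an age effect — and every
stage is validated against that truth.

# Coordinate and unit conventions

Masks are logical matrices whose first index runs along x (rightward from
the top-left origin) and second along y (downward); a continuous
coordinate (x, y) falls in pixel `(floor(x)+1, floor(y)+1)`. Transcript z
is a 1-based plane index. All physical distances are computed in one
place as `sqrt((dx*pixel_size)^2 + (dy*pixel_size)^2 + (dz*z_spacing)^2)`
with defaults `pixel_size = 0.5` µm and `z_spacing = 1.5` µm (stacks of
6–7 planes spaced 1.5 µm are the acquisition geometry this emulates).
Keeping a single conversion point avoids pixel/µm drift between modules.

# The synthetic generator

`simulate_cell()` grows a soma disk plus `n_primary_branches` biased random
walks from the soma rim (heading jitter `0.35*(tortuosity-1)+0.02`
radians per unit step; one optional secondary branch with probability 0.3
at midpoints), dilates the skeleton to `branch_width`, and replicates the
2D shape across planes with 20% per-plane erosion of the process boundary.
The soma is held fixed across planes so soma/process partition the total
mask on every plane — which makes count conservation an exact, testable
invariant rather than an approximation. Defaults (soma radius 8 px = 4 µm;
ramified cells 5 branches of mean length 30 px = 15 µm; amoeboid cells one
8 px stub) sit in the range of adult mouse microglia at 0.5 µm/px. The
amoeboid default keeps a minimal process so that genes with finite
placement log-odds never request placement in an empty compartment.

`simulate_transcripts()` draws per-gene Poisson counts, sends each molecule
to the process with probability `sigmoid(process_logodds)`, and places it
uniformly in that compartment's voxels — or as a Thomas process when
`cluster_sigma > 0` (parents uniform in the compartment; offspring
isotropic in-plane Gaussians, redrawn until inside the mask; offspring
stay on their parent's plane because decoded molecules live on discrete
planes). Genes with a `coloc_partner` share the partner's parent points,
which plants co-localization without forcing marginal clustering levels
apart.

`age_effect()` multiplies |log-odds| by `enrichment_attenuation`
(default 0.5) and retains `ceiling(fraction * P)` of the planted pairs
(default 0.25, chosen to match the roughly four-fold drop in significant
pairs between young and aged networks). Expression level is *not* coupled
to shape by default; analyses that need shape-linked expression (the
classifier, held-out clustering) plant it explicitly at the panel level,
so each experiment controls exactly one effect.

What the generator does not emulate: microscope PSF and shot noise,
3D arbors that change topology across planes, segmentation errors of the
boundary polygons, and cell-to-cell contamination other than the optional
astrocyte blob. Green tests therefore certify the statistical machinery
and its calibration, not robustness to real-microscopy artifacts.

# Segmentation choices

The coarse segmenter follows histogram equalization → 8-bit quantization →
white top-hat background subtraction → noise suppression → Gaussian blur
(σ = 2 px) → Otsu → connected components, with two numerical choices worth
stating. First, a pixel is suppressed as noise only when it is **both**
below the Otsu threshold of the Sobel edge image **and** below the Otsu
threshold of the background-subtracted intensity: suppressing on edge
magnitude alone hollows flat stain interiors into rings and fragments one
cell into several labels, which the mutual-uniqueness matching rule then
discards. Second, components under 64 px are dropped: histogram
equalization stretches flat background noise across the full range, and a
minimum size is the standard speckle cleanup.

Matching keeps a (label, cell) pair iff the boundary overlaps exactly one
label and that label exactly one boundary, with an optional annotation
filter; ambiguity is dropped, not resolved. Refinement defines the soma as
the nuclear∩microglial-stain component containing the matched coordinate
(local-mean adaptive threshold, 200 px window, offset 2/255; a 5 px
neighbourhood vote tolerates single-pixel holes at the exact center), the
per-plane process as the fine-window (50 px) microglial mask minus soma
minus the fine-window astrocyte mask, and the total as soma ∪ subtracted
process — *post*-subtraction, so `soma + process = total` holds exactly
per gene and molecules removed by subtraction are "unassigned". GFAP is
subtracted from processes only (the text this emulates describes process
subtraction; soma identity is already anchored on the nuclear stain).

# Morphometry

The canonical 26 features are fixed as: area/perimeter of cell, convex
hull and soma; solidity, convexity, roughness, circularity
(4πA/P²), span ratio, convex circularity, eccentricity, Euler number,
extent, soma ratio, Feret diameter; skeleton length, mean branch length,
branch/branching-point/terminal-point counts; fractal dimension,
lacunarity, tortuosity. Sholl scalars (ramification index, critical
radius, dendritic maximum), per-branch Euclidean/path distances and mean
stain intensity are computed but reported as a supplementary block — the
canonical/supplementary split is this package's own stable convention.

Numerical details:

* **Perimeter** is the 8-connected outer-contour chain length scaled by
  0.98; the raw chain overestimates smooth digitized boundaries by ~4%,
  which would push an ideal disk's circularity to ~0.92.
* **Skeletons** come from Zhang–Suen thinning. Degrees on the skeleton
  graph drop a diagonal adjacency when its two pixels already share an
  orthogonal on-pixel (staircase corners are paths, not junctions);
  terminals have degree 1, branching points ≥ 3, and branches are the
  components left after removing branching points. Tortuosity is mean
  path/chord over branches.
* **Fractal dimension** is box counting on dyadic sizes 2 … side/4, grid
  anchored at the bounding-box corner with no offset averaging; the
  analytic anchors (filled square → 2, line → 1, Sierpinski depth 7 →
  log 3/log 2) are regression-tested with tolerances that absorb
  anchoring effects.
* **Lacunarity** is the gliding-box statistic at box size ⌈side/8⌉ with
  population variance, so a filled mask gives exactly 1.
* **Sholl** counts connected components of the skeleton inside annuli of
  half-width √2/2 (an 8-connected path cannot skip such an annulus; a
  1 px annulus misses diagonal crossings). The ramification index is the
  literal radius ratio — critical radius over first non-zero radius — not
  the more common intersection ratio.

The embedding backend resizes each mask-bounded crop to 112×112
(preserving aspect), pads with middle gray to 224×224, and concatenates a
16×16 mean-pooled intensity grid with a 16×16 mean-pooled gradient-
magnitude grid: exactly 512 deterministic values. It is a handcrafted
multiscale descriptor fulfilling the same length/preprocessing contract a
pretrained convolutional backend would; no weights are downloaded and the
whole pipeline stays reproducible offline. Clustering runs PCA to 10
components, k-means over k = 1…10 (10 restarts, seed-derived), a Kneedle
elbow pick on the inertia curve (sensitivity 1), and relabels clusters
C1…Ck by ascending mean terminal-point count with mean cell area as the
tie-break.

# Expression statistics

QC keeps cells with ≥ 20 transcripts and ≥ 5 detected genes (inclusive).
Normalization is `ln(1 + 1e4 · count/total)` — natural log for the layer,
log2 only for fold changes. Differential expression is a two-sided
Mann-Whitney test per gene (normal approximation with tie correction),
BH-adjusted, with `log2FC` computed on depth-normalized means
(`expm1` of the lognorm values) and a 1e-9 pseudocount; the DEG rule is
the strict `|log2FC| > 1 and padj < 0.05`. Compartment enrichment
log-normalizes soma and process counts independently and tests process vs
soma on the most ramified classes only. Tau specificity is
Σ(1−x̂)/(N−1) with the published thresholds (specific: subclass τ ≥ 0.85
with the target as argmax; ubiquitous: τ < 0.80 at both levels). Gene-set
scoring subtracts expression-matched controls drawn from 25 mean-
expression bins, 50 per set gene, *excluding the set itself* (widening
the bin window when a bin holds nothing else); without that exclusion a
strongly shifted set saturates its own bins and the score collapses.

# Correlation, classification, distance CDFs

Spearman correlations are computed only on a seeded 75% training split;
held-out cells are reserved for the two-group average-linkage clustering,
whose agreement with the amoeboid (C1∪C2) vs ramified (C3–C5) partition
is summarized by the adjusted Rand index. Top-k ranking uses |ρ| (the
source describes "top correlating" without a sign; signed ranking is a
flag), first-k after a stable sort. The classifier is a ranger random
forest on process-enriched gene expression, seeded 80/20 split, tuned by
5-fold CV accuracy over a deliberately small fixed grid
(trees ∈ {100, 300}, depth ∈ {∞, 10}), reporting held-out AUROC and
impurity importances normalized to sum to 1. Transcript distances are
in-plane distances to the soma centroid divided by the cell's maximum
centroid-to-mask distance; uniform placement in a disk has CDF x², the
analytic anchor used in validation.

# Spatial statistics

The 3D Ripley estimator is `K(r) = V/(n(n−1)) Σ 1[d ≤ r]` with
`H(r) = (3K/(4π))^{1/3} − r` (the 3D variance-stabilized transform,
centered at 0 under CSR). No edge correction is applied *by design*: the
Monte-Carlo null redraws the same number of points uniformly in the same
compartment voxel set, so boundary bias cancels in the envelope
comparison. Significance at radius r means the observed H leaves the
pointwise 5%/95% null quantiles. For processes the statistic is computed
per individual process (connected component) and averaged. Calibration
uses radii of 3–7 µm at ~100 molecules per compartment; at sub-µm radii
expected pair counts are below 1 and tie-induced discreteness makes the
envelope conservative — a property of all envelope tests on sparse counts,
documented rather than hidden.

Co-localization uses the 5th percentile (linear interpolation) of pooled
within-soma pairwise distances as the radius, counts cross-gene molecule
pairs within it (same-gene pairs excluded), and builds the null by
redrawing every molecule uniformly within its own compartment (per-gene
counts preserved; 1,000 randomizations at full scale). Per cell, a
z-score per pair (zero-sd pairs skipped); across cells counts and z are
averaged and a one-sided upper p is recomputed from the averaged z — the
literal reading of averaging statistical measures; Stouffer combination
is available as a flag. An edge requires all three criteria
conjunctively: average count ≥ the 90th percentile of non-zero average
null contacts, ≥ 4 cells with an observation, and BH-adjusted p < 0.05;
components of ≤ 2 genes are dropped; each remaining component is
clustered by a Gaussian mixture on a 2-eigenvector spectral embedding of
the z-weighted adjacency, with the component count chosen by BIC over
k = 1…min(5, nodes) — the mixture counts in the source were set manually,
so an information criterion replaces that judgment call.

# Validation experiments and problem sizes

The experiment drivers in `R/experiments.R` (also used by
`scripts/acceptance.R` and `tests/testthat/test-acceptance.R`) run at the
package's standard sizes: 500 CSR genes and 100 Thomas genes at 200-draw
envelopes for Ripley calibration/power; 20 planted and 20 CSR datasets of
50 cells at 200 randomizations for co-localization recovery; 200 ramified
cells with |log-odds| = 2 planted genes for enrichment recovery; 200
cells per class with a four-fold planted shift for the classifier; 5,000
molecules for the distance-CDF check. The 200-draw randomization depth is
a scaled-down version of the full 1,000-draw procedure with the same
quantile structure; all Monte-Carlo stages derive their streams from one
seed plus a stage tag and are exactly reproducible.

# Known limitations

* The embedding is not a learned representation; it separates shape
  classes that differ in multiscale mass/gradient structure but will not
  replicate the feature space of a pretrained network.
* Envelope tests are conservative at radii with expected pair counts
  near zero; choose radii so that expected counts exceed a few pairs.
* The GFAP subtraction inherits the stain's own threshold errors — on
  real tissue it cannot remove astrocyte territory the stain misses.
* Cross-plane structure is replication with boundary noise; true 3D
  arbor reconstruction is out of scope.
* `mww_de` fold changes are compositional (depth-normalized): planting a
  large shift in a small panel induces apparent opposite shifts in the
  remaining genes; panels of ≥ ~100 genes keep that artifact below the
  DEG threshold.
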