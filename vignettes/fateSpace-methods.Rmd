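---
title: "Methods: spatial analysis of intermingled fate specification"
author: "fateSpace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of intermingled fate specification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fateSpace)
```

# The question and the data

Planarian neoblasts — the adult pluripotent stem cells of *Schmidtea
mediterranea* — commit to one of many tissue fates by expressing
fate-specific transcription factors (FSTFs). Two competing spatial
pictures exist: fate choices could be made in spatially coherent clusters
(for instance, driven by local niches), or they could be intermingled,
with neighboring stem cells freely adopting divergent fates. The
distinction is a statistical one about a labeled 3D point pattern: given
cell centroids and class labels, do same-class cells neighbor each other
more than exchangeable labels would?

`fateSpace` operates at the segmented-cell level: per-cell 3D centroids
(micrometres), optional radii, and integer transcript counts per gene.
Everything upstream (imaging, decoding, segmentation) is out of scope.
Axes follow x = mediolateral, y = anteroposterior (anterior = +y),
z = dorsoventral.

# Classification model

Cells are classified by threshold rules over pooled marker counts, pools
being defined by a `MarkerPanel` (one pool per fate class and mature
tissue, plus the 13-gene neoblast core containing the pan-neoblast gene
*smedwi-1*).

* **Neoblast**: pan-neoblast count ≥ `smedwiMin` (default 5) **and**
  pooled count over the other 12 core markers ≥ `neoblastOtherMin`
  (default 6). We interpret the "additional neoblast marker" threshold as
  applying to the pooled sum over the non-*smedwi-1* core genes, not
  per-gene; the pooled reading is the only one compatible with the
  reported mean of 37 additional transcripts against a threshold of 6.
* **Specialized neoblast**: among neoblasts, total FSTF count
  `T ≥ fstfTotalMin` (default 5, inclusive, since totals *below* 5 are
  excluded) and a *strict* majority (> 50%) for a single fate pool. Exact
  ties between top pools are unassigned — a tie carries no single-fate
  evidence.
* ***smedwi-1*-low progenitor**: pan-neoblast count in 1–4 (the band
  below the neoblast bound but with detectable signal; cells with zero
  pan-neoblast transcripts are never called, as there is no evidence they
  derive from a neoblast) plus a passing fate signature.
* **Mature cell**: among non-neoblasts, the top mature pool if it holds
  ≥ `matureMin` (default 5) transcripts and a strict majority of
  mature-pool counts. This rule is our own symmetric construction: a
  count-only pipeline cannot use the anatomical-position criteria that
  accompany marker pools in imaging-based classification, which is a
  deliberate divergence and a known limitation.

All thresholds live in `classifierConfig()` (units: transcripts/cell,
except the dimensionless majority fraction). The rules are deterministic
and monotone: adding core transcripts can never revoke a neoblast call,
and adding majority-pool transcripts can never unassign a specialized
cell (both are property-tested).

# Synthetic tissue generator

The generator exists so every downstream statistic can be validated
against known ground truth. It emulates the *structure* of segmented
spatial-FISH data, not its imaging physics.

**Positions.** Nuclei centroids are approximately hard-core; we sample by
uniform dart-throwing with rejection (candidates closer than `minSep` to
an accepted point are discarded), defaulting to `minSep` = 10 µm — one
neoblast cell diameter, read off the equivalence of 72 µm with about 7
cell diameters; the default cell radius is correspondingly 5 µm and is
used only for surface-to-surface distances. Dart-throwing is not an exact
Poisson-disk process, but at the packing fractions used (a few percent)
the difference is immaterial, and a feasibility guard plus a bounded
attempt budget (`10000·n`) turn pathological requests into explicit
errors. Cell number density is a free configuration parameter: the source
material does not state one, so defaults (e.g. 2000 cells in a 300³ µm
box) were chosen to reproduce realistic inter-nucleus spacings of
~15–20 µm and kept fixed.

**Labels.** Three regimes:

* *i.i.d.* (the intermingled null): every cell draws its label from the
  homeostatic class-frequency table. The published frequencies are
  epidermal 0.30 and muscle 0.05 (proportions among all neoblasts); the
  remaining mass is split intestine 0.10, CNS 0.10, protonephridia 0.05,
  eye 0.02, pharynx 0.03, unassigned 0.35 — a configuration choice (only
  the first two are printed) fixed once and not tuned.
* *clustered* (the alternative): `parentsPerClass × nClasses` parent
  points are scattered uniformly, with per-class parent counts
  apportioned (largest remainder, ≥ 1 per class) proportional to the
  class frequencies so that marginal label frequencies converge to the
  table; each cell takes its nearest parent's label, producing contiguous
  single-fate domains of unambiguous spatial scale. A `gaussian-weight`
  mode softens this with kernel length scale σ and converges to the
  i.i.d. regime as σ grows.
* *target-biased*: class weights are `freq · (1 + (E − 1)·e^{−d/λ})`
  with `d` the distance to the class's target primitive. The functional
  form was chosen so that enrichment `E = 1` reduces *exactly* to the
  i.i.d. regime (the two regimes share one inverse-CDF sampler and are
  draw-for-draw identical at `E = 1`, which is tested), `E` is the
  enrichment factor at the target surface, and the bias decays with
  length λ.

**Counts.** Independent Poisson counts per gene; each label × component
mean is split uniformly over the component's genes. Defaults are
calibrated to the reported conditional call statistics: neoblast labels
emit mean 8 pan-neoblast + 37 pooled-core transcripts, all non-neoblast
labels 1 + 8; specialized neoblasts add mean 10 in their own FSTF pool
and 0.5 in each other FSTF pool (markers enriched in, but not exclusive
to, a class). Unassigned neoblasts emit no FSTF signal: the recovery
guarantees below presume well-separated emission, and a background FSTF
rate on unassigned cells is a user-settable deviation rather than a
default. Counts are Poisson rather than negative-binomial because only
conditional means are available to calibrate against and the classifier
consumes thresholded sums; an optional `dispersion` parameter switches to
negative-binomial with the same means when overdispersion matters.

Note that truncation makes the *conditional* means slightly exceed the
emission means: among cells passing the ≥ 5 threshold, mean *smedwi-1* is
`E[X | X ≥ 5] ≈ 8.5` for `X ~ Poisson(8)`. Both are within the ±15%
calibration band the tests enforce.

**What passing tests do not show.** The generator draws positions
uniformly (no anatomy-correlated density gradients), emits counts
independently across genes (no cell-size or detection-efficiency
covariates), and uses geometric primitives for tissues. Tests passing on
these fields validate the statistical machinery, not robustness to
segmentation errors, spot misassignment, or anisotropic tissue
organization in real specimens.

# Neighborhood statistics and the permutation null

**Nearest neighbors** use squared-distance argmin over all pairs
(blockwise for memory), with ties broken by the smallest cell index, and
an optional surface mode `max(0, d − r_i − r_j)`.

**Voronoi neighborhoods.** Neighbors are cells whose Voronoi regions
share a facet. We compute facets directly: for a candidate pair, the
shared facet is the part of their bisector plane closer to the pair than
to every other cell, clipped to the bounding box; it is evaluated as a 2D
convex polygon via Sutherland–Hodgman clipping (in C++), and the pair is
adjacent iff the facet area exceeds `facetTol` = 1e−9 µm², which
suppresses numerically degenerate faces. Numerical choices:

* *Clipping box*: the data bounding box padded by one mean NN spacing by
  default. Cells whose region touches the box are flagged `boundary` and
  excluded as query cells from neighborhood composition (their regions
  are truncation artifacts), while remaining available as neighbors.
  Whether the original analyses used periodic or clipped boundaries is
  not documented; clipping with explicit flags is the conservative
  choice. For interior cells the clipped adjacency equals the Delaunay
  adjacency exactly; boundary cells can lose far-flung facets, so tests
  compare against an independent Delaunay oracle as a subset plus exact
  interior-row equality, and verify full equality under a clip box padded
  far beyond the data.
* *Candidate pruning*: each cell's facets are searched among its 40
  nearest cells (all cells when n ≤ 41, making small cases exact); the
  maximum Voronoi degree observed in hard-core uniform fields is far
  below 40.
* *Degeneracy*: 2–4 points form valid clipped tessellations and are
  accepted; from 5 points up, a fully coplanar or collinear cloud is
  rejected as degenerate input.

**Composition.** For a query class, NN mode reports stacked percentages
of nearest-neighbor labels (the "self" percentage being the fraction of
query cells whose NN shares their class); Voronoi mode reports per-cell
neighbor-label fractions and their histogram over an exact-zero bin plus
ten equal bins on (0, 1] (the ridgeline data; the original binning is not
printed, and a dedicated zero bin keeps "no same-class neighbor at all"
visible). Unassigned neoblasts are included as potential neighbors by
default — they are part of the cell field — and can be excluded by
filtering labels upstream.

**Permutation null.** Positions (hence the NN map) stay fixed; labels are
permuted without replacement `nShuffles` = 1000 times with a dedicated
seeded stream per analysis call, and the query class's self-NN percentage
plus its full neighbor-label composition are recorded per shuffle. Under
exchangeability the self-NN expectation for a class of size `k` is
`100·(k−1)/(n−1)`, which the implementation reproduces within Monte-Carlo
error (tested); on nearest-parent clustered fields the observed statistic
exceeds the 97.5th null percentile in ≥ 90% of replicates at the tested
field sizes, while on i.i.d. fields the 95% interval has calibrated
type-I error.

# Tissue distances

Point-set tissues use nearest-centroid distance; geometric primitives use
exact closest-point formulas (plane, cylinder tube with optional axial
extent, segment, solid sphere). The pharynx is special: progenitors enter
only through the esophagus on the anterior cavity face and do not cross
the cavity, so the relevant quantity is the shortest cavity-avoiding
path. We compute it in the body plane (the construction is planar; the
dorsoventral coordinate is dropped for this one measurement): the
straight segment to the esophagus if it does not cross the open cavity
interior, else the minimum over visible cavity corners of the straight
leg plus the shorter perimeter path to the esophagus. Queries posterior
to the cavity may route around either side; the minimum-length route is
returned, resolving the tie the verbal "nearest border intersection"
description leaves open. Crossing detection uses Liang–Barsky clipping
with an open-interior midpoint test, so segments that merely touch a
corner or run along a border are not "crossings". Queries inside the open
cavity are rejected.

# Reproducibility and problem sizes

Every stochastic function is a pure function of its inputs and an integer
seed; the pipeline runner derives per-stage seeds from one master seed by
a stable string hash (`deriveSeed`), so adding an analysis stage never
perturbs earlier stages, and rerunning a configuration reproduces outputs
byte for byte. The test suite exercises calibration at sizes chosen to
make its statistical bounds sharp while staying desk-scale: fields of
1000–2000 cells for null calibration (200 replicates) and power (100
replicates), 10,000 cells for emission calibration, 100 random small
fields (n ≤ 50) against the Delaunay oracle, and 200 obstructed queries
across 20 random cavity geometries against a brute-force route
enumeration.

# Known limitations

* Mature-cell calling ignores anatomy; real analyses combine markers
  with stereotypical positions.
* The classifier is rule-based by design; no mixture-model or
  probabilistic assignment is offered.
* Poisson emission underestimates count dispersion of real FISH data
  unless the dispersion parameter is raised.
* Voronoi adjacency is computed in a clipped box; boundary-cell
  adjacency is truncation-dependent and such cells are excluded as
  queries by default.
* The pharynx routing is planar; a genuinely 3D obstacle geometry (or
  arbitrary mesh anatomy) is out of scope, as is Ripley's-K style
  machinery — the statistics here are NN- and tessellation-based only.
* Hypothesis tests on exported distance samples (t-tests, ANOVA) are
  deliberately delegated to standard routines; the package exposes the
  samples.
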