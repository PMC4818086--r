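---
title: "Methods: 3D morphometry of epithelial structures with sama3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of epithelial structures with sama3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epithelial cells grown in 3D matrices (collagen, reconstituted basement
membrane) organise into acini and ducts whose shape responds to hormonal
and pharmacological treatment: elongation, lateral branching, and the
formation of a hollow lumen are the morphogenetic readouts of interest.
Confocal z-stacks of such cultures contain hundreds of structures, far too
many for manual scoring, and 2D projections systematically mis-measure
elongation and cannot see lumena at all.  `sama3d` reconstructs every
structure in a stack in 3D, measures a standard panel of shape descriptors,
and compares populations of structures across experimental conditions.

The pipeline has three stages: image preprocessing that homogenises the
stack until a single threshold segments the structures; per-structure
measurement (morphometrics, lumen analysis, skeleton-based branching); and
a statistics layer that consolidates all structures into one table,
compares conditions and reports distribution curves, boxplots and a PCA
overview.

## Shape descriptors

For each 26-connected structure (after per-slice hole filling, so the
cavity does not interfere with size and shape):

* **Volume** `V`: voxel count times the physical voxel volume.
* **Principal semi-axes** `L >= M >= S`: from the eigen-decomposition of
  the spacing-aware second-moment matrix of the voxel centres, with
  `semi_axis = sqrt(5 * lambda)` — the solid ellipsoid whose moments match
  the object's.  A half-voxel correction (`spacing^2 / 12` added to the
  moment diagonal) removes the bias of sampling a solid at voxel centres;
  without it a 3-voxel semi-axis is underestimated by about 2%.
* **Elongation** `Elon1 = L / M` and **flatness** `Elon2 = M / S`; a duct
  has `Elon1 > Elon2`, a plate the opposite, a sphere both equal to 1.
* **Sphericity** `S = ((36 pi V^2) / A^3)^(1/3)`, 1 for a perfect sphere.
* **Ratio volume ellipsoid** `RVE = V / (4/3 pi L M S)`: about 1 for
  convex ellipsoidal bodies, towards 0 for branched or concave shapes.
* **Relative lumen volume** `RLV`: total cavity volume over the filled
  structure volume, in `[0, 1)`.
* **Quality** `Q = Elon1 - Elon2 + 5 RLV`: positive for elongated,
  lumen-bearing ("normal") epithelial structures, negative for flat ones.
* **Complexity** `C`: cumulated physical length of all skeleton branches.

The surface area `A` in the sphericity is computed with a smoothed-gradient
(co-area) estimator: the binary mask is convolved with a 1-voxel Gaussian
and the gradient magnitude of the result is integrated over the volume.
For a smoothed indicator this integral equals the average area of its level
surfaces, so it is an almost unbiased surface estimate; raw voxel-face
counting overestimates a sphere's area by ~50% and would push sphericity to
about 0.8 for a perfect sphere, destroying the anchor `S = 1`.  The
estimator's curvature bias is second order (about +1% for a radius-10
sphere), which is why the package's sanity anchor demands a rasterized
sphere score within `[0.97, 1.02]`.

One printed formula deserves a note: the tabulated definition of RLV reads
"volume of the structures with lumen / volume of the lumen", while the
descriptive text defines the ratio of lumen volume to structure volume.
The two directions are mutually inverse; `sama3d` implements
`RLV = lumen / structure`, because only a ratio bounded in `[0, 1)` makes
the quality score `Q = Elon1 - Elon2 + 5 RLV` behave as described (a lumen
can then contribute at most 5 to `Q`).  The inverse is available as the
derived column `structure_to_lumen_ratio`.

## Tier-1 preprocessing

Low-magnification confocal stacks are noisy, unevenly lit and dimmer at
depth.  Tier 1 is fully automated and mandatory; all radii are exposed in
`tier1_config()`:

1. **Local background subtraction** (`subtract_background()`): per-slice
   grayscale opening (minimum-then-maximum filter) with a large window,
   default half-width 25 voxels.  The window must exceed the widest
   structure cross-section; anything narrower than the window survives
   subtraction unchanged.
2. Optional **denoise hook**: any `function(stack) -> stack` (an external
   wavelet or bilateral denoiser can be plugged in; none ships with the
   package, and the default is off).
3. **3D rank filtering** (`rank_filter_3d()`): median (radius 2 by
   default) on the morphometrics branch; median radius 1 on the lumen
   branch.  The gentler lumen-branch median is deliberate: a radius-2
   median over a 5^3 box fills in cavities whose smallest semi-axis is
   under ~2.5 voxels, erasing exactly the signal the lumen stage needs.
   Minimum/maximum/variance filters can be appended via
   `extra_filters`.  Rank filters use a cubic box neighbourhood (fast and
   separable for min/max), not a ball; results differ marginally at these
   radii.
4. **Gaussian smoothing** (`gaussian_blur_3d()`): separable, sigma 1 in
   physical units, converted per axis by the voxel spacing — the only
   spacing-aware filter, mirroring the voxel-based originals.
5. **Depth-luminosity compensation** (`compensate_depth()`): the robust
   maximum (99.9th percentile, hot-pixel resistant; the exact maximum is a
   config option) of each slice is smoothed by a running mean over the
   slice and its two neighbours; each slice is scaled to bring that
   running average to its stack-wide maximum.  Gains are capped at 10x so
   near-empty slices are not amplified into pure noise.
6. **Structure mask**: threshold (Otsu by default, or a fixed value) and
   per-slice hole filling.
7. Optional **gradient separation** (`gradient_separation()`): the 3D
   morphological gradient is subtracted from the image, which removes thin
   bright necks between conjoined structures; only needed for crowded
   images and off by default.

After labeling, each structure's mask is repaired in isolation
(`solidify_labels()`): the cropped mask is closed (maximum-then-minimum
filter, radius 2) and re-filled.  The closing seals thin shell breaches: a
structure whose lumen sits close beneath the surface can, after smoothing
and thresholding, open a small channel from cavity to exterior; the broken
hollow shell then defeats hole filling, shrinks the measured volume, and
its skeleton degenerates into a mesh of spurious branches.  Repairing
*per structure*, after labeling, is essential — the same closing applied
to the whole mask before labeling bridges structures that sit two or three
voxels apart and destroys the object count.

The lumen branch of the pipeline runs stages 1-5 but never fills holes, so
the interior darkness that defines a cavity is preserved.

## Lumen analysis

A lumen is a dark region forming a hole inside a structure.  Candidate
cavity voxels are those inside the filled structure mask but below the
lumen threshold on the lumen-branch image; candidates are 26-connected
components of at least 27 voxels (a 3-voxel cube).  The threshold varies
between images and is therefore user-set (`"otsu"` is the automatic
default).  Each lumen is assigned to the structure containing its centroid
(majority overlap as fallback); unassignable lumena are flagged and
excluded rather than silently dropped.  Per-slice (2D) filling is the
default for parity with the per-slice pipeline heritage; volumetric (3D)
filling is a config alternative — the two differ for cavities open at the
top or bottom slice, where 2D filling still closes the in-slice rings but
3D filling does not.

## Skeletons and complexity

Each structure's filled mask is thinned to a curve skeleton by a
topology-preserving algorithm: voxels are peeled from the six faces in
turn, and a voxel may only be deleted if it is a (26,6) simple point (its
foreground neighbours form one 26-component and the local background one
face-connected 6-component) and not a curve endpoint.  Deletion therefore
never splits a structure, never loses one, and never opens a tunnel;
solids collapse to their medial curves by rim erosion.  Skeleton voxels
are classified by neighbour count (1 endpoint, 2 path, 3+ junction);
branches are maximal paths between nodes, with physical lengths (diagonal
steps weigh `sqrt(2)` or `sqrt(3)` times the spacing).  Conventions fixed
here because no published convention exists: an unbranched duct counts as
one branch (the "I" case); an isolated voxel is a single zero-length
branch; a closed loop contributes one branch of its perimeter length.
Junction-to-endpoint spurs shorter than 2 voxels are pruned — thinning on
bumpy rasterized surfaces produces 1-2 voxel spurs, and this default makes
a rasterized ellipsoid report exactly one branch while leaving genuine
arms (which are several voxels long) untouched.

Branch *counting* on voxelised, smoothed bodies is where iterative
thinning fails, in both directions.  A slight surface bump on a
near-spherical structure grows a medial fork several voxels long that a
fixed prune cannot distinguish from a real branch; conversely, where two
thick ducts cross, the thinning front rounds the junction into a smooth
elbow and one arm is absorbed before it can thin to a curve, so a
genuinely branched structure reads as unbranched.  We verified both
failure modes on rasterized ellipsoid pairs, with this package's thinning
and with an independent reference implementation of Lee-style thinning,
which collapses such pairs to one or two voxels.

The pipeline's complexity stage therefore derives its branch graph from a
*geodesic centreline tree* (`measure_complexity(method = "geodesic")`,
the default; `centerline_tree()`), in the spirit of path-based centreline
algorithms: the voxel farthest from the centroid and the voxel farthest
from it are the first two tips; their geodesic path (26-connected,
Euclidean step weights so digital paths stay straight) is the initial
centreline; further tips are accepted greedily while the candidate —
the voxel geodesically farthest from the current tree — protrudes from
every straight chord between accepted tips by more than twice the
structure's inscribed-ball radius.  The threshold is scale-free and
separates bodies from appendages: the rim of any solid ellipsoid leaves
its long-axis chord by at most the middle semi-axis, which in this
generator's size range never exceeds the inscribed diameter, whereas a
crossing duct's third tip does.  Every significant arm ends in a tip and
is guaranteed its branch; surface bumps never spawn one.  A final
thinning pass removes the occasional redundant voxel where a digital
path turns.  `skeletonize_3d()` (thinning) remains available and is the
`method = "thinning"` alternative.

## The phantom generator

Because no public microscope data accompany the method, validation runs on
computer-generated stacks with exact ground truth.  A phantom stack is a
population of randomly placed, randomly oriented (uniform rotations via
unit quaternions), randomly sized solid ellipsoids; each may contain a
concentric ellipsoidal cavity whose semi-axes are a single uniform
fraction of the parent's.  Four conditions mirror the validation design:

* **C1** (reference): 40 ellipsoids per stack, semi-axes uniform in
  `[6, 12]` voxels, every structure hollow.
* **C2**: the sampling maximum of one designated semi-axis is doubled
  (`[6, 24]`) — more elongated structures.
* **C3**: each structure has only a 50% chance of a lumen.
* **C4**: each structure is two perpendicular duct-like ellipsoids: both
  parts draw their designated (long) semi-axis from the widened `[6, 24]`
  interval, and the second part is rotated 90 degrees about a random axis
  orthogonal to the first's designated direction and centred at the tip
  of that designated semi-axis — a T junction of crossing ducts.  Both
  choices are deliberate design decisions for a condition whose purpose
  is to carry measurably higher complexity.  A *concentric* perpendicular
  union is simply a rounder blob: its curve skeleton is no more complex
  than a single ellipsoid's (we measured a lower multi-branch rate than
  for singles).  And a T of *stubby* parts (every semi-axis in `[6, 12]`,
  aspect at most 2) is skeleton-indistinguishable from a single body: the
  rim of an ellipsoid protrudes from its centreline by up to its middle
  semi-axis, exactly the range a stubby arm protrudes, so no branch
  detector can separate the two — reference thinning implementations
  collapse such pairs to one or two voxels.  Branched epithelial ducts
  are slender; with duct-like parts the condition produces the branched
  skeletons it is meant to probe (multi-branch rate ~0.33 and mean branch
  count ~2.4 vs 0.00 and 1.00 for the reference condition, on clean
  rasterized populations).

Values the validation design leaves open were fixed once, for
morphometric stability at desk-scale runtime: grid 64 x 256 x 256 voxels
with unit spacing; foreground (shell) intensity 200 and background 20 on
an 8-bit-like scale; lumen radius fraction uniform in `[0.35, 0.6]`, so
cavities are strictly interior; six stacks per condition.  Structures are
placed by rejection sampling with at least 2 voxels of clearance, because
count recovery is part of the validation and presumes separable
structures.  Stacks are clean by default — artifacts (additive Gaussian
noise, per-slice geometric depth decay) are opt-in via `apply_artifacts()`
so the preprocessing stages can be exercised deliberately; whether the
original validation stacks carried noise is not recorded, and clean
defaults make the ground truth exact.

What the phantoms do *not* emulate: optical point-spread blur, spectral
channels, tile stitching, partial-volume texture inside structures, or
biological shape irregularity.  Passing the phantom validation therefore
demonstrates that segmentation, measurement and statistics recover known
geometry and known contrasts — it does not certify performance on any
particular microscope's noise or resolution regime.

## Statistics

All structures from all stacks are consolidated into one table (condition,
replicate, stack, label, parameters).  Group summaries report mean, sample
SD, coefficient of variation and median per condition x replicate.
Hypothesis tests compare per-stack means by default — the stack is the
experimental replicate; pooling individual structures treats
non-independent observations as replicates and is available only behind an
explicit pseudo-replication warning.  Conditions are compared with one-way
ANOVA and, when exactly two conditions are present, a two-sided Wilcoxon
rank-sum test that is exact (full enumeration of all `choose(n+m, n)`
labelings, midranks for ties) for group sizes up to 10; the **reported
p-value is the larger of the two** — a deliberately conservative
convention.  With 6 stacks per condition the exact two-sided Wilcoxon
floor is `2/924 ~ 0.00216`, which is why completely separated conditions
report p = 0.002 at three decimals.  Tests are two-sided throughout, and
no multiple-testing correction is applied to the per-parameter reports
(matching the per-parameter reporting convention; a Benjamini-Hochberg
adjusted column can be added trivially from the tidy output).

The PCA overview standardises the selected parameters (correlation-matrix
PCA), drops zero-variance variables with a warning, and plots the
correlation circle and the per-structure scores coloured by condition.
Reproducibility curves are kernel density estimates of a parameter for
each replicate, sharing one Silverman's-rule bandwidth per condition so
the curves are comparable; superimposed curves indicate reproducible
replicates.  As a quantitative diagnostic the pairwise Kolmogorov-Smirnov
distance between replicate samples is reported — a package choice, since
no published overlap statistic accompanies the original curves.

## Numerical choices and degenerate inputs

* Rank-filter and convolution edges are handled by mirror reflection.
* Otsu's threshold maximises between-class variance on a 256-bin
  histogram; `binarize()` records the value actually applied.
* Components need at least 64 voxels (about 4 voxels across) by default;
  moment measurement of fewer than 4 voxels is a hard error.
* Ties in the axis ordering are resolved by the stable eigenvalue sort, so
  a perfect sphere reports `Elon1 = Elon2 = 1` exactly.
* An all-zero slice in depth compensation would produce an infinite gain;
  gains are capped (default 10x) with a warning.
* Structures touching the stack border are kept by default
  (`exclude_border = TRUE` drops them): the validation phantoms never
  touch the border, and for real stacks the choice is the user's.
* End-to-end determinism: all randomness lives in the phantom seeds, so
  identical config + identical inputs reproduce every CSV byte for byte.

## Problem sizes used in the shipped checks

The full validation study (4 conditions x 6 stacks x 40 structures at
64 x 256 x 256) runs in 10-15 minutes on one core and is what the
acceptance script executes.  The package's own test suite runs that
study once and otherwise exercises the same code paths on smaller grids
(for example 40 x 96 x 96 with 6-8 structures, and 20-seed binomial
sweeps for the lumen-probability recovery), sizes chosen so the whole
suite stays well inside half an hour while every contrast the validation
relies on is still visible.

## Known limitations

* The curve skeleton of a near-spherical body is a short segment whose
  length is sensitive to voxelisation; complexity comparisons are
  meaningful between conditions, not as absolute lengths.
* Per-slice hole filling cannot close a cavity that is open in every
  slice containing it (a breach spanning the full z-extent); the binary
  closing stage makes this rare but a pathologically thin shell can still
  leak.
* The Wilcoxon normal approximation (groups > 10) is standard but
  approximate near p = 1; exact enumeration covers every design the
  validation uses.
* `RVE` uses the moment-matched ellipsoid, which is not the minimum
  enclosing ellipsoid; branched structures score lower than 1 on both
  definitions, but the absolute values differ.
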