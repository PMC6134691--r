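---
title: "Shape retrieval from projection images: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape retrieval from projection images: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A single-particle electron microscopy experiment observes 2D projections of
an unknown 3D density. Given only a handful of class-average-like projection
images, one would like to propose candidate 3D shapes from a catalogue of
known low-resolution envelopes. `shapesearch` implements that retrieval
pipeline end to end: it normalizes a collection of 3D density maps to a
common grid and particle volume, removes redundant shapes, simulates a
library of projection images from the survivors, and ranks library models
against query images with a standardized match score.

Because the interesting properties of the method are geometric rather than
data-set specific, the package ships a parametric phantom generator
(spheres, ellipsoids, cylinders, dumbbells, L-blocks, bullet shapes) so that
every stage is testable without downloading any archive data.

## Size normalization

Shape, not size, is the retrieval criterion: two maps that differ only by a
scale factor should be treated as the same entry. Maps are first resampled
to a standard cubic grid (100 voxels of 1 Å; the content is scaled
isotropically so its largest physical extent fills the box, and the density
is renormalized so total mass is conserved). Each map is then converted to a
Gaussian mixture model (GMM) and its particle volume $V_{old}$ estimated,
after which the map is resized to the reference particle volume
$D_{ref}^3 = 50^3\,\text{Å}^3$ using the axis-dimension rule

$$D_{new} = D_{old} \times \frac{D_{ref}}{\sqrt[3]{V_{old}}},$$

with $D_{old} = 100$ Å. We interpret $D_{new}$ as a resize target: the
content is scaled by $D_{new}/D_{old}$ about the box center inside the fixed
100 Å box. The 50 Å reference leaves margin around the particle in the
64×64-pixel projections. Content pushed outside the box by upscaling is
cropped symmetrically with a warning (peripheral density does occur in real
maps); a $D_{new} > 4 D_{old}$ is rejected as an implausible volume.

**Volume from a GMM.** How the upstream tools derive a volume from a mixture
is not published, so the package defines it explicitly: the volume of the
isodensity region containing 95% of the mixture's mass, evaluated on a 1 Å
grid (densities sorted in decreasing order and voxels counted until the
cumulative mass reaches the target). The definition is threshold-free,
reproducible, and scale-covariant *for scaled copies of the same map*. Note
a subtlety verified by the tests: a *fixed-width* soft edge attached to
shapes of different sizes breaks scale covariance of any mass-fraction
measure — the edge region holds a relatively larger mass fraction on a small
particle. The scale-invariance tests therefore use true scaled copies (the
soft edge scales with the shape); with mixed resolutions, absolute volumes
carry a size-dependent bias of order the edge width.

## Gaussian-mixture shape similarity

A map is summarized by $K$ weighted Gaussians (default 20; 40 for large
collections) fitted by expectation–maximization on voxel centers weighted by
density, with k-means++ initialization (refined by a few Lloyd iterations — a
well-placed start roughly halves the EM iteration count) from an explicit
seed, a relative log-likelihood tolerance of $10^{-6}$ (500 iterations
maximum), and maps downsampled to at most 64 voxels per axis before
fitting. Covariance eigenvalues are floored at 0.25 Å² so components cannot
collapse onto sharp features. Voxels below $10^{-3}$ of the map maximum are
excluded from the fit; for maps with an additive noise floor the threshold
should be raised to about twice the noise SD (`threshold` argument), since
clamped background noise would otherwise claim a double-digit percentage of
the mixture mass and inflate the volume estimate. The volume-estimation
grid is capped at ~8 million voxels (the spacing coarsens beyond that), so
a diffuse fitted component cannot exhaust memory.

Similarity of two mixtures $f_A, f_B$ is the overlap correlation

$$CC = \frac{\int f_A(\mathbf r)\, f_B(\mathbf r)\, d\mathbf r}
{\sqrt{\int f_A^2 \, d\mathbf r \int f_B^2 \, d\mathbf r}},$$

whose numerator has the closed form
$\sum_{k,l} w_k w_l\, \mathcal N(\mu_k - \mu_l;\, 0,\, \Sigma_k + \Sigma_l)$.
The analytic value is validated against 3D Riemann quadrature to $10^{-6}$
relative error. Superposition maximizes CC over *proper* rigid transforms of
the second mixture (reflections are never searched): four principal-axis
sign alignments plus seeded random rotations (24 starts by default; the
denominator is rotation invariant, so only the cross term is re-evaluated),
each refined by Nelder–Mead on a rotation-vector/translation
parameterization. The returned CC is never below the unaligned CC.

## Projection library

View directions are vertices of a subdivided icosahedron in polar
orientation (so $+z$ is always a vertex), restricted to the upper
hemisphere: the projection along $-\mathbf v$ is the mirror of the
projection along $+\mathbf v$, and the 2D aligner searches mirror states, so
the lower hemisphere is redundant. The smallest subdivision with enough
vertices is pruned to the requested count (91 by default; 196 for denser
coverage) by farthest-point selection seeded at $+z$ — deterministic, and
quasi-uniform by construction. The exact angular scheme used by the original
projection tool is not published; the counts are reproduced, the individual
directions need not be.

A projection is computed by sampling the map in a rotated frame (trilinear
interpolation) and integrating along the view axis in 1 Å steps onto a
64×64 raster covering the 100 Å field of view (1.5625 Å/pixel). Pixel
values are line integrals (density × Å); their sum is direction independent
to < 1% (mass conservation), which is the invariant the tests pin down.

**Interpolation order.** Established map-processing pipelines typically use
cubic splines for 3D resampling. This implementation uses trilinear interpolation for all
3D resampling and projection: it vectorizes cleanly in R at $100^3$ scale
and is accurate for the smooth, soft-edged envelopes this method targets
(mass drift < 1%, projection symmetry errors < 1% RMS in the tests). 2D
image rotation uses bilinear interpolation — cheap and adequate for
low-resolution shapes.

## 2D alignment

The similarity of two images is the maximum zero-mean, unit-norm
cross-correlation inside a centered circular mask of radius 30 px (of 64),
searched exhaustively over in-plane rotation (2° steps by default), mirror,
and translations up to 10 px. The mask removes corner content that rotation
padding would otherwise move in and out of frame. The translational search
is an exact *masked* normalized cross-correlation: for every shift the
window mean and variance of the stack image under the translated mask are
computed by FFT, so an integer translate of the reference scores exactly 1.
Conventions (tested): `psi` rotates the query counterclockwise before
correlation; mirroring flips the query's x axis before rotation; the
returned shift applies to the rotated query. When one image is scanned
against a whole stack, the single reference is rotated into its search
variants once instead of rotating every stack image — equivalent up to
interpolation because the mask is isotropic, and roughly two orders of
magnitude cheaper at library scale.

## Redundancy reduction and clustering

Pairwise superposed CCs are mapped to distances $d = \sqrt{1 - CC^2}$
(superposition CCs are floored at 0: nonnegative mixtures cannot produce
meaningful negative overlap, and $CC^2$ would conflate $\pm CC$ anyway).
Clustering is agglomerative Ward in the **ward.D** sense — the
Lance–Williams update applied to *unsquared* distances — implemented
directly with deterministic lowest-index tie-breaking and validated against
R's independent `hclust(method = "ward.D")`. The tree is cut at the median
merge height ("the point at which half of the structures cluster"), and
each cluster is represented by its **medoid** (member minimizing summed
distance to co-members; lowest id on ties) — the reference method does not
state its representative rule, and the medoid is deterministic and
geometry-aware. Duplicated shapes merge at height 0, so a fully duplicated
collection halves, mirroring the published archive-scale reduction.

## Retrieval scoring

For query image $i$ and library image $j$, $CC_{i,j}$ is the maximum
alignment correlation. Each query row is standardized,

$$Z(i,j) = \frac{CC_{i,j} - \mu_i}{\sigma_i},$$

which equalizes the contribution of each query image regardless of contrast
or absolute correlation level (multiplying one query's contrast by any
positive constant leaves its Z row unchanged). Per model $n$ the top
$k = 10$ Z-scores of each row are summed to $X_i^n$ (models with fewer than
$k$ images contribute all of them, with a warning), $S_n = \sum_i X_i^n$,
and the final match score standardizes over models:

$$T_n = \frac{S_n - \mu_S}{\sigma_S}.$$

$\sigma$ is the population standard deviation (divide by $N$) in both
standardizations — the source formulas do not specify, and a sample-SD
switch is exposed. $T_n$ is monotone in $S_n$, so the ranking is identical
under either. Ties in the top-$k$ and in the ranking break by column index
and model id. Consecutive-score gaps are reported but not classified: no
published threshold separates "well-suited" matches, so that judgement is
left to the user.

## What the synthetic generator does and does not emulate

`make_density` produces an indicator solid smoothed by a Gaussian soft edge
(2 Å default, emulating the smooth falloff of low-resolution envelopes)
with optional additive, zero-clamped Gaussian noise — deterministic given a
seed. Fixture libraries draw shapes round-robin from families with ~12%
size jitter and random orientations. This reproduces the *geometry* of the
retrieval problem (distinct shape families, arbitrary pose, redundancy) but
not CTF effects, solvent noise spectra, fractional occupancy, or the
heterogeneous voxel sizes and box dimensions of archive maps. A green
retrieval test therefore establishes that the pipeline's geometry and
scoring are correct, not that archival hit lists would be reproduced
number-for-number.

**The acceptance library is a curated, non-redundant set.** Early fixture
libraries drew family members by random size jitter; after volume
normalization (which removes overall scale) members of a family ended up
with superposed overlap CCs of 0.95-0.99 — far more redundant than a real
deduplicated library, whose retained entries share CC below about 0.9. In
that regime self-retrieval is ill-posed: the exact query match scores 1.0,
but a near-duplicate sibling's views score 0.998+, and the top-10 sum
decides by noise. The shipped fixture (`distinct_shape_specs()`) therefore
spans *structurally* different regimes — sphere, prolate/oblate/triaxial
ellipsoids, disk-to-rod cylinders, dumbbell variants, L-blocks, a capped
rod — the synthetic analog of the redundancy-reduced library on which the
retrieval protocol is designed to operate. A related coupling matters for
view density: the top-10 per-model sum presumes each model has on the order
of ten views near any query view, which holds at the production 91 views
per model but not with very sparse view sets; the acceptance library
therefore halves view density (48 per model) and no more.

Reduced acceptance scale (fixed in the test helpers): the 20 curated
models, 48 projections per model, $K = 6$ components, 6 superposition
starts, 6° rotational step. At this scale self-retrieval must be perfect
(20/20 models ranked first from 5 of their own library images) and mildly
perturbed held-out variants of a library shape (~10% size jitter, new
random orientation, 5% additive clamped noise) must rank their source model
in the top 3. Noisy queries are prepared the standard way before fitting:
`denoise_map()` low-pass filters the map (2 Å) and subtracts the background
pedestal (the median voxel value — clamped noise has a positive mean that
smoothing turns into a near-uniform offset), after which a 1% density
threshold suffices; this keeps the soft edge and makes the query's volume
estimate consistent with the library's own.

## Known limitations

- Absolute CC values differ from the original third-party binaries
  (different EM initialization, rotational step, and mask policy); the
  properties and orderings are what is guaranteed.
- The 95%-mass volume is a stand-in for an unpublished definition; absolute
  volumes on mixed-resolution inputs carry an edge-width bias (see above).
- Anisotropic-spacing maps are rescaled isotropically by their largest
  extent (aspect ratio preserved), not axis-stretched.
- No CTF simulation or Fourier-space (diffraction) patterns; heterogeneous
  query sets (mixtures of conformations) are not modelled.
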