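---
title: "Bifurcation-based fundus image registration: models and design"
author: "fundusreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifurcation-based fundus image registration: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusreg)
```

## The problem

A pair of colour fundus photographs of the same retina — taken minutes or
months apart, from slightly different fixation angles or devices — must be
brought into a single coordinate frame before they can be compared,
mosaicked, or fused. Fundus images are poor material for general-purpose
feature detectors: most of the frame is smooth, texture-poor background
inside a dark circular field of view (FOV), and generic corner detectors
concentrate points on the FOV rim where they are useless for alignment.
The retinal vasculature, however, is a stable, patient-specific structure,
and its *bifurcations and crossovers* are well-distributed, repeatable
landmarks. `fundusreg` implements a landmark pipeline built entirely on
them:

1. coarse vessel segmentation on the inverted green channel,
2. skeletonization and hit-or-miss junction detection,
3. gradient-orientation (HOG) description and cross-checked
   second-nearest-neighbour matching,
4. similarity/affine estimation by distance-constrained RANSAC,
5. Laplacian-pyramid blending of the warped pair,

plus the standard evaluation protocol (per-pair control-point error,
success curve over 0–25 px, normalized AUC) and a seeded synthetic
generator that makes every stage testable without any external data.

## Vessel segmentation

Vessels absorb green light, so the analysis surface is the inverted green
channel, zeroed outside the FOV, Gaussian-smoothed (`sigma = 1.5` px),
white-top-hat filtered with a disc of radius 9 px (removing smooth
illumination while keeping structures up to roughly twice that width), and
contrast-stretched with 3% of pixels saturated at each tail. All
pixel-unit defaults are defined at a working scale of ~1024 px FOV
diameter; larger images are downscaled first and the fitted transform is
mapped back to native resolution. The smoothing and top-hat radii are not
prescribed by the method's published description; the values above were
chosen to preserve vessels up to ~18 px wide at working scale and are
exposed in `pipeline_config()`.

Segmentation then rests on two statistics of the enhanced image:

* **Global threshold** `tau_i`. With `f(l)` the CDF of in-FOV intensities
  and `Delta_f = f(255) - f(0)`, the threshold is the level maximizing the
  distance between the CDF curve and the straight line joining its
  endpoints on the unit square,

      tau_i = argmax_l | f(l) + Delta_f (1 - l/255) - 1 | / sqrt(1 + Delta_f^2).

  As printed in the source description the numerator uses `(1 - l)` with
  `l` in 0–255, which is dimensionally inconsistent with `f(l)` in [0,1];
  we normalize the intensity to `l/255`, reading the construction as a
  point-to-line distance between two curves on the unit square. Ties break
  toward the smaller level.

* **Window threshold** `tau_sd`. A normalized gray-level co-occurrence
  matrix (NGLCM) is accumulated over *all eight* neighbour directions at
  distance 1 (hence symmetric) and normalized to a joint probability.
  `P_bg` sums the probability that two adjacent pixels both lie below
  `tau_i`, and with `corr` the NGLCM correlation,

      tau_sd = floor( P_bg * corr * n^2 ),

  the maximum number of background-intensity pixels tolerated in an
  `n x n` window before its centre pixel is classified background. A
  negative correlation would give a negative pixel count, so it clamps to
  zero. The window size is not prescribed; the default `n = 7` is
  comparable to the widest vessels at working scale. A constant image has
  an undefined correlation and raises a typed error rather than silently
  substituting a value.

The classifier is a pixel-by-pixel window vote: windows are clipped at the
frame border and out-of-FOV pixels count as background, deliberately
biasing the rim — where FOV edge artifacts live — toward background.
Raising `tau_sd` can only grow the vessel set (monotonicity, covered by a
property test). On the default synthetic fundus the vessel fraction inside
the FOV lands at ~15%, inside the 10.4–14.9% range reported for real
fundus imagery (the tests assert a deliberately broad 5–25% band). The
published method's subsequent morphological reconstruction from a
curvature map is intentionally omitted: the coarse map alone detects a few
extra non-junction points along vessels, which are harmless — any
repeatable point helps the later stages.

## Skeleton and bifurcations

Zhang–Suen thinning reduces the vessel mask to a one-pixel skeleton: two
alternating sub-passes delete boundary pixels whose neighbour count lies in
2–6, whose ring transition count is exactly 1, and whose north/south/east/
west triads satisfy the sub-pass conditions, until a fixed point. Deletions
within a sub-pass are simultaneous. Two properties are worth knowing:
the skeleton is idempotent under re-thinning, and connectivity is preserved
in the sharp sense that no component ever splits or merges — but compact,
hole-free blobs (starting from the classical isolated 2×2 block) can erode
away entirely. The test suite asserts exactly this sharp version against an
independent literal transcription of the published sub-pass rules.

Junctions are located with the hit-or-miss transform: a pixel is flagged
when the skeleton matches a foreground stencil B1 and its complement
matches a background stencil B2 simultaneously. The default bank holds
nine 3×3 ternary stencils — four rotations of the axis-aligned T junction,
four rotations of the diagonal Y junction, and the + cross — with
don't-care corners keeping the patterns mutually exclusive. The published
figure defining the bank is not machine-readable, so the shapes here are a
reconstruction, and one choice deserves its rationale: the "diagonal Y" is
encoded as *two perpendicular axis branches plus the opposing diagonal*
(e.g. west, south, north-east), not as two adjacent diagonal branches.
Tabulating skeleton neighbourhoods at known junctions of thin synthetic
trees shows thinning strongly prefers axis-connected branches: with this
encoding the bank detects ~90–94% of true junctions within 3 px, against
~77% for the adjacent-diagonals variant. The bank is serializable to JSON
so users can supply their own.

Detections closer than 5 px merge to their centroid snapped back to the
nearest skeleton pixel (noise makes junction evidence multi-pixel), and
points within the top-hat radius of the FOV boundary are discarded — the
rim otherwise produces junction-like artifacts.

## Description and matching

Each keypoint is described by the classical 128-dimensional layout: a
16×16 patch (keypoint at offset (8,8)), standardized to zero mean and unit
variance — which makes the descriptor exactly invariant to gain and offset
of the local illumination — centred-difference gradients, sixteen 4×4
cells each contributing an 8-bin orientation histogram of gradient
magnitudes (45° bins, hard assignment), concatenated, L2-normalized,
clipped at 0.2 and renormalized. No dominant orientation is assigned:
same-session fundus pairs rotate by only a few degrees, and the similarity
model absorbs what remains. The descriptor is therefore *not*
rotation-invariant beyond roughly ±10–15°; this is a documented limitation,
not an accident.

Matching uses the second-nearest-neighbour criterion with a cross-check
(only pairs found in both directions survive; the result is one-to-one).
The published description sets "a threshold of 0.2 … as a fraction of the
magnitude of the most similar vector", which supports two readings; both
are implemented behind `mode`:

* `"magnitude"` — accept when `d1 <= 0.2 * ||b1||`, i.e. an absolute
  distance threshold for unit-norm descriptors (the literal reading);
* `"ratio"` — the classical distinctiveness test `d1/d2 <= threshold`.

Measured on synthetic pairs, distances for *geometrically true*
correspondences concentrate around 0.3–1.0 and their nearest/second ratios
never fall below ~0.3 — under either reading a 0.2 threshold accepts
nothing. The package therefore defaults to ratio matching at 0.9:
deliberately permissive, because with a few dozen weakly-distinctive
landmarks the selectivity belongs to the cross-check and to RANSAC, not to
the ratio test. Ties in nearest-neighbour distance break toward the lower
index, making matching deterministic.

## Transform estimation

Similarity (4 DOF, minimal sample 2) and affine (6 DOF, minimal sample 3)
models are fitted as `p_target = T p_source` on homogeneous coordinates.
Minimal fits are exact; larger sets are solved by linear least squares;
coincident or collinear source points raise typed errors. RANSAC draws
minimal samples whose source points are pairwise at least 50 px apart
(rejection sampling, 100 retries per iteration): spreading the sample
curbs the leverage that landmark localization error exerts on the model.
Matches within 5 px reprojection error count as inliers — well above
localization jitter, well below a mismatch — and the best consensus set
(ties by lower mean error) is refit by least squares. The iteration budget

    N = ceil( log(1 - p) / log(1 - (1 - v)^m) ),   p = 0.99

adapts to the best inlier ratio found so far (the published description
leaves open whether N is fixed a priori; adapting is standard practice)
and is capped at 10,000. A single integer seed drives all sampling, so
registration is reproducible bit for bit.

## Blending

The warped source and the target are fused per pyramid level as
`(L_A M_A + L_B M_B) / (M_A + M_B)` where the mask sum is positive and 0
elsewhere. Laplacian levels come from blur-then-decimate downsampling and
bilinear upsampling, so collapsing a pyramid reconstructs its input to
floating-point accuracy; masks ride down the same pyramid, turning binary
support into fractional weights at coarse levels — that widening of the
transition band is precisely what removes the seam while the
normalization preserves exposure and prevents overflow. Three octaves by
default; with one octave the method degenerates to per-pixel weighted
averaging (a closed form the tests exploit). Colour images blend per RGB
channel; blending in a luminance space was considered and rejected to keep
the mosaic's channels independent and the operation invertible per
channel.

## Evaluation protocol

Given ground-truth control points (ten per pair in the FIRE convention,
whitespace text files `x_src y_src x_tgt y_tgt`), the registration error
is the mean Euclidean distance between transformed source points and their
target counterparts, in native pixels. The success curve evaluates
`rate(t) = fraction of pairs with error <= t` on the integer grid
t = 0..25 px — inclusive, so the t = 0 column is meaningful for exact
registrations — and the AUC is the trapezoidal integral normalized by 25.
Pairs whose RANSAC fails score as failures at every threshold rather than
being dropped. Batches are stratified by category (S/P/A-style prefixes)
with min/max/mean/SD over the successful pairs per category.

## The synthetic generator

`generate_tree()` grows a binary branching tree: trunks leave a small
circle near the canvas centre, each segment splits into two children at
20–50° off the parent with geometrically shrinking lengths, widths
tapering 6 to 2 px, every split recorded as a ground-truth junction
(`n_roots (2^(depth-1) - 1)` of them). `render_fundus()` composes the dark
surround, a circular FOV disc, a reddish background with a smooth radial
illumination falloff, vessels darker in green than background (so the
inverted green is vessel-bright), an optional 1-px central reflex stripe
along wide vessels, and Gaussian noise. `make_pair()` plants a similarity
(scale 0.95–1.05, rotation within ±10°) or affine (shear up to 0.05)
transform about the canvas centre and solves the translation magnitude
against the two-disc overlap formula so the FOVs overlap by ~85%
("high", the >75% regime of same-session pairs) or ~55% ("low", the
mosaicking regime). The target view is rendered *from the transformed tree
geometry* with its own camera-centred FOV rather than by resampling the
source image: that reproduces how a refixated camera actually sees the
scene, involves no interpolation, and makes the ten control points sampled
in the overlap exact by construction
(`registration_error(true_model, control_points)` is identically 0).

Default conditions: 768×768 canvas, 700 px FOV, `n_roots = 6`,
`depth = 6`, trunk length 120 px — about 186 branch points, comparable to
the landmark density of real fundus images at working scale. These
defaults, like the transform magnitudes, were fixed while designing the
generator, as the conditions the test suite then runs under.

What the generator deliberately does **not** model: vessel curvature and
tortuosity, calibre variation along a vessel, the optic disc and macula,
pathology (microaneurysms, cotton-wool spots), camera vignetting beyond a
radial polynomial, and chromatic noise correlation. Passing tests on this
material therefore demonstrates the pipeline's geometric and statistical
correctness — repeatable detection, correct matching, robust estimation,
seamless blending — not clinical-grade segmentation of real retinas, where
curvature-based refinement and learned segmenters are known to do better.

## Problem sizes and runtime choices

The test suite registers twenty seeded high-overlap noiseless pairs at the
default 768 px canvas (a few seconds per pair), runs 100-trial RANSAC
recovery and noise-sensitivity simulations, and checks every brute-force
oracle on small grids (8×8 co-occurrence images, 24×24 skeletons, 32×32
window classifications). `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

## Known limitations

* Descriptors are not rotation- or scale-invariant; pairs rotated beyond
  ~15° or scaled beyond ~10% will lose matches. The published method
  shares this property.
* Only similarity and affine models are provided. The retina is a curved
  surface; both models leave a floor of reprojection error that grows with
  eccentricity, and quadratic or eye-model approaches are explicitly out
  of scope.
* Junction localization on thick vessels is displaced by a few pixels
  toward the parent branch (the two child lumens merge before the
  centrelines do). The displacement is consistent between the two views of
  a pair, so matching and estimation tolerate it, but single-image
  junction coordinates should not be read as sub-pixel ground truth.
* The low-overlap regime with few crossings can leave RANSAC with too few
  spread-out matches; such pairs report `converged = FALSE` and score as
  failures rather than returning a bad matrix.
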