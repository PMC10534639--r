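# fundusreg

Feature-based registration of colour retinal fundus photograph pairs,
using blood-vessel **bifurcations and crossovers** as landmarks.

Fundus photographs show a texture-poor retina inside a dark circular field
of view; generic corner/blob detectors either starve there or pile points
onto the FOV rim. The vascular tree, in contrast, is a stable,
patient-specific structure whose junctions make well-distributed,
repeatable landmarks. `fundusreg` implements the full landmark pipeline —
for ophthalmic image analysts who need to mosaic fundus images, align
longitudinal series, or benchmark registration methods — along with an
evaluation protocol and a synthetic ground-truth generator:

1. **Coarse vessel segmentation.** On the smoothed, top-hat-filtered,
   contrast-stretched inverted green channel, a global threshold is taken
   where the intensity CDF is farthest from the line joining its
   endpoints,
   `τᵢ = argmax_l |f(l) + Δf·(1 − l/255) − 1| / √(1 + Δf²)`,
   and a windowed classifier counts sub-threshold pixels in each `n × n`
   window against `τ_sd = ⌊P_bg · corr · n²⌋`, where `P_bg` and `corr`
   come from an omnidirectional normalized gray-level co-occurrence
   matrix (distance 1).
2. **Landmarks.** Zhang–Suen thinning to a one-pixel skeleton, then the
   hit-or-miss transform `A ⊛ B = (A ⊖ B1) ∩ (Aᶜ ⊖ B2)` against a bank of
   nine junction stencils (T×4, Y×4, +).
3. **Description & matching.** 128-dimensional HOG descriptors
   (16×16 patch, 4×4 cells, 8 orientation bins), second-nearest-neighbour
   matching with cross-check.
4. **Estimation.** Similarity or affine `p₂ = T·p₁` by RANSAC with
   `N = ⌈log(1−p) / log(1−(1−v)^m)⌉` adaptive iterations and a minimum
   distance constraint between sampled matches.
5. **Blending.** Mask-normalized Laplacian-pyramid fusion,
   `(L_A·M_A + L_B·M_B)/(M_A + M_B)` per octave, for a seam-free mosaic.
6. **Evaluation.** Mean control-point registration error per pair, success
   curve over 0–25 px thresholds, normalized AUC, stratified by category.

See `vignettes/fundusreg-methods.Rmd` for the models, parameter defaults
and design rationale.

## Worked example

Everything below runs offline: the pair is synthesized with a known
(planted) transform and ten exact control points.

```r
library(fundusreg)

pair <- make_pair(seed = 42, kind = "similarity", overlap = "high")
pair
#> <synthetic_pair seed=42> similarity transform, high overlap (measured 0.88)

reg <- register_pair(pair$source, pair$target, blend = TRUE)
reg
#> <fundus_registration>
#>        kp_source        kp_target  matches_forward matches_backward
#>               82              107               64               78
#>          matches          inliers
#>               53               50
#> <registration_result> similarity, 50/53 inliers

registration_error(reg$result$model, pair$control_points)
#> [1] 0.357
```

82 and 107 bifurcations were detected in the two views; cross-checking the
64 and 78 one-directional matches leaves 53 candidates, of which RANSAC
accepts 50 as inliers. The fitted matrix reproduces the planted one to the
third decimal — scale 0.9514 vs 0.9506 planted, identical rotation — and
the mean error over the ten ground-truth control points is 0.36 px.
`reg$mosaic` holds the blended mosaic (write it with
`write_image_png()`); `success_curve()` and `evaluate_batch()` score
whole datasets.

A command-line front end wraps the same functions:

```sh
SCRIPT=$(Rscript -e 'cat(system.file("scripts", "fundusreg", package = "fundusreg"))')
Rscript $SCRIPT synth  out/data --n 3 --seed 1
Rscript $SCRIPT register out/data/S001/source.png out/data/S001/target.png out/reg
Rscript $SCRIPT evaluate out/data out/eval
```

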