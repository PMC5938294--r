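---
title: "Automated ureteral stone measurement and passage prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ureteral stone measurement and passage prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whether a ureteral stone will pass spontaneously depends strongly on its
size and position in the ureter, and the predicted probability feeds
directly into the decision between conservative surveillance and
intervention. Stone size, however, is measured by hand on CT reformats,
and different radiologists measure differently. Because the prediction
curve for upper ureteral stones is steep in exactly the 4–6 mm range where
many upper stones live, millimetre-scale reader disagreement can translate
into very large disagreement in predicted prognosis. `lithometry`
implements the full computational chain needed to study this:

1. automated 3D stone segmentation from a CT volume,
2. six size estimates derived from the segmentation,
3. logistic passage-probability curves calibrated from published anchor
   probabilities, and
4. simulators (digital stone phantoms, virtual readers, synthetic
   cohorts) plus the statistical toolkit (ROC/AUC, Bland–Altman,
   percentage-point binning, Friedman's rank test) used to quantify the
   impact of reader variability.

## Segmentation model

The working representation is a `ct_volume`: a 3D attenuation grid in
Hounsfield units with per-axis spacing in mm, world coordinates at voxel
centers, 0-based index arithmetic, right-handed axes. Segmentation runs in
five deterministic steps:

* **Crop** to a rectangular region of interest around the stone. The ROI
  is operator input (the package does not localise stones); a half-extent
  of ~5 mm around the stone center is ample.
* **Resample** to 0.25-mm isotropic voxels by trilinear interpolation.
  Trilinear is the standard choice for CT resampling (no ringing, exact on
  locally linear fields); out-of-grid samples clamp to the edge, which is
  immaterial because the ROI always pads the stone. Interpolation weights
  are renormalised by their computed sum so constant plateaus — and hence
  the half-maximum threshold below — are numerically exact.
* **Threshold** at `max(max_HU / 2, 200)`: half of the maximum attenuation
  in the ROI (taken after resampling), floored at 200 HU so image noise
  cannot enter faint stones. The comparison is inclusive (`>=`), which
  makes the 400-HU boundary case deterministic.
* **Component selection**: thresholding "stone plus surroundings" can pick
  up other bright islands, so only the 26-connected component containing
  the attenuation peak is kept. 26-connectivity is the most permissive
  standard choice and keeps faceted digitized stones whole.
* **Dilate** with a digital ball of radius 2 voxels (0.5 mm; 33 voxels
  including the center). The half-maximum rule finds the "core" edge of a
  blurred stone; the dilation compensates the resulting negative bias
  relative to manual bone-window measurements.

All measures are computed on the dilated mask, and the mask's provenance
records the applied threshold and dilation radius.

## The six size estimates

* **Length**: the largest Euclidean distance between two *border points*
  (occupied voxels with an unoccupied 6-neighbour; the strictest digital
  surface). This is the 3D Feret diameter; the implementation reduces
  large point sets to their convex hull first (the diameter is attained at
  hull vertices) and is tested for exact equality against an O(n²) scan.
  The long axis is the unit vector joining the achieving pair, with exact
  ties broken lexicographically.
* **Width**: planes perpendicular to the long axis are sampled every
  0.25 mm along the stone, each plane resampled at 0.25 mm in-plane by
  trilinear interpolation of the occupancy thresholded at 0.5 (standard
  multiplanar reformation; nearest-neighbour lookup would thicken oblique
  sections by up to half a voxel diagonal and bias areas upward by 2–3%).
  The width is the maximum over planes of the in-plane Feret diameter —
  a supremum definition that is rotation-stable.
* **Cross-sectional area and circumference** are reported at the plane of
  maximal occupied area (deterministic and stable on lumpy masks, where a
  centroid-plane convention is not). Area is pixel count × pixel area.
  Circumference is the perimeter of the marching-squares 0.5-level contour
  of the section, computed after a light Gaussian pre-smoothing (σ = 1 px)
  so contour vertices interpolate to sub-pixel positions; contouring the
  raw binary staircase overestimates a smooth perimeter by ~6%, and
  pixel-edge counting by up to 4/π. For sections too small for the
  smoothed field to reach 0.5 the raw contour is used (a single pixel thus
  measures the diamond through its edge midpoints, ≈0.71 mm).
* **Volume**: the volume enclosed by the tight single-region surface
  around the segmented voxels *as cubes* equals the voxel-union volume,
  so it is computed directly as voxel count × voxel volume. A surface
  through the voxel *centers* is bounded by their convex hull and
  necessarily loses a half-voxel rind — about −7% on a 3-mm-radius
  digitized sphere at 0.25-mm voxels — whereas the voxel-union volume is
  within ~1%.
* **Surface area** is reported from the enclosing convex hull of the voxel
  centers (an in-package incremental 3D hull). For the convex-leaning
  shapes of urinary stones the hull tracks the physical surface closely
  (−4% on the digitized sphere), while a staircase voxel surface would
  overestimate it by up to √3. The exported point-set operation
  `alpha_shape_metrics()` is the same hull construction; for markedly
  concave masks it overestimates the enclosing surface, a documented
  limitation.

Accuracy on noiseless digitized ellipsoids is characterised by the
phase-averaged absolute error over six sub-voxel digitization phases,
because a single phase carries ±1–2% of noise through the Feret-axis
estimate: the longest border-point chord of a digitized ellipsoid tips
diagonally across the flattened caps, tilting the measured axis by up to
~0.1 rad, an effect intrinsic to the Feret definition of the long axis. At
0.25-mm voxels the mean errors for a 10 × 6 × 4 mm ellipsoid are ~0.19 mm
(length), ~0.04 mm (width), ~1.5% (area), ~1.2% (circumference) and
~0.8% (volume), and the mean errors shrink monotonically over
0.5 → 0.25 → 0.125 mm. These numbers are recomputed by the test suite.

## Virtual caliper and window settings

Manual measurements depend on the display window: a reader measures to the
apparent stone edge, which sits where the attenuation profile crosses a
window-dependent level. `virtual_caliper()` models this as the super-level
set `{HU >= level}` of the volume (component containing the peak) measured
with the same geometric operators — level 300 for the bone window
(L300/W1120), level 50 for the soft-tissue window (L50/W400). On a
Gaussian-blurred phantom the apparent diameter matches the blurred
step-edge crossing to within the digitization tolerance, and the
soft-tissue level always shows at least as large a stone as the bone
level.

## Passage-probability curves

The published prediction curves for spontaneous passage within 20 weeks
are available only through probabilities printed at specific sizes, so the
package reconstructs each curve as a two-parameter logistic model
calibrated through those anchors on the logit scale — an exact solve for
two anchors, least squares on logits for more. The shipped anchor file
(`inst/extdata/passage_anchors.json`, versioned) carries the width/bone
anchors: upper ureter 73% at 4.2 mm and 35% at 5.0 mm; lower ureter 88% at
4.2 mm and 62% at 6.0 mm. The reconstruction is validated by the printed
worked example: the upper curve calibrated on its two anchors predicts
6.7% ≈ 7% at 6.0 mm, a 66-ppt spread between the 4.2-mm and 6.0-mm
estimates, while the lower curve spreads only 26 ppt over the same range —
the steepness asymmetry that drives everything downstream. Anchors for
other measure/window combinations were never published; the package
accepts user-supplied anchor sets for them and deliberately ships no
invented defaults. Sizes outside the anchor range extrapolate on the logit
scale and are flagged in the prediction's metadata. Reported percentages
round half-up to the nearest integer.

## What the simulators emulate — and what they do not

`phantom_spec()`/`synth_stone_volume()` digitize a triaxial ellipsoid
(peak attenuation on a soft-tissue background, default 1000/40 HU) at an
anisotropic acquisition grid (default 0.7 × 0.7 × 1.0 mm), blur with an
isotropic Gaussian point-spread function and add Gaussian noise. Ellipsoids
are chosen because every measure has a closed form (volume 4/3·π·abc,
surface by Thomsen's approximation, p = 1.6075). The phantoms do *not*
emulate ureter/bone anatomy, scanner reconstruction kernels, beam
hardening, or lobulated calculi (a perturbation hook exists but is off by
default) — so passing tests demonstrate correctness of the geometry
pipeline, not clinical segmentation robustness.

`cohort_params()`/`synth_cohort()` draw a cohort matching the study
population descriptors: 391 stones, 32% upper ureter, bone-window widths
Normal(4.7, 1.7) mm upper and Normal(3.3, 1.4) mm lower, truncated below
at the 2-mm inclusion limit (exact inverse-CDF truncation), and
length/width ratio log-normal with median 1.3 and σ_log = 0.2 floored
at 1 — the ratio law is this package's own default, as no joint
length–width distribution was published. Three virtual readers add
per-reader bias and Gaussian noise to the true size (floored at 0.5 mm):
biases (0, 0.7, 0.6) mm and SDs (0.53, 0.40, 0.40) mm, solved from the
published pairwise 95% limits of agreement for width (0.7 ± 1.3, 0.7 ± 1.3,
0.1 ± 1.1 mm); the printed bias triangle is not exactly consistent, and
(0, 0.7, 0.6) is the closest consistent triple. The same noise magnitudes
are reused for length, for which no limits were published. Outcomes are
pure Bernoulli draws from the location-matched 20-week curve at the true
width; follow-up horizons are labels, with no censoring or intervention
model.

Because outcomes are *generated from* the same curves used downstream, the
simulated AUCs and agreement statistics describe the simulation, not the
clinical cohort: the real-cohort values (AUC 0.88–0.90, limits of
agreement 0.2 ± 1.1 / 0.2 ± 1.4 mm, >20-ppt fractions 44%/6%, median
spreads 17/16/16/12 ppt) derive from unavailable patient data and travel
through `run_study()` only as labelled reference annotations, never as
targets or assertions. What the simulation *does* reproduce structurally
is the variability asymmetry: upper stones show a far larger fraction of
>20-ppt prediction spreads than lower stones, the spread grows
monotonically with reader noise, vanishes exactly at zero noise, and
collapses when the flat lower curve is assigned to both locations —
demonstrating that curve steepness, not the location label, is the
mechanism.

## Statistical operators

* **ROC AUC** with DeLong 95% confidence intervals via the `pROC` package
  (orientation: smaller size predicting passage is concordant); the test
  suite checks exact equality with exhaustive concordant/discordant pair
  counting (ties credited 0.5).
* **Bland–Altman**: bias ± 1.96 × sample SD of paired differences.
* **ppt bins**: `<20, 20–40, 40–60, 60–80, >80`, half-open on the right
  so a spread of exactly 20 ppt lands in 20–40 (the first bin is strictly
  "< 20"), the last bin closed at 100.
* **Friedman's rank test** is implemented in-package because the base-R
  version omits the tie correction: within-subject mid-ranks,
  χ² = (k−1)·Σ(Rj − n(k+1)/2)² / (Σrij² − nk(k+1)²/4), k−1 degrees of
  freedom. For n < 8 subjects the χ² approximation is replaced by a
  seeded within-row Monte-Carlo permutation p-value (2000 permutations).
  Null calibration is verified at the secondary-analysis problem size
  (124 subjects × 4 estimates), where the rejection rate at α = 0.05 is
  within Monte-Carlo error of 0.05.

## Worked example

```{r}
library(lithometry)

# a 6 x 4 x 3 mm stone, blurred and noisy, on a 0.7 x 0.7 x 1 mm grid
ph <- synth_stone_volume(phantom_spec(c(3, 2, 1.5), peak_hu = 900,
                                      psf_sigma = 0.4, noise_sd = 15,
                                      seed = 7))
mask <- segment_stone(ph$volume, roi_box(c(0, 0, 0), c(5, 5, 5)))
mask$provenance$threshold_hu
measure_stone(mask)

# passage prediction for the measured width
model <- calibrate_from_anchors(passage_anchors("upper"))
predict(model, 5.0)
```

```{r}
# a small simulated reader-variability study
rep <- run_study(study_config(cohort = cohort_params(n = 400)), seed = 17)
rep
```

## Numerical choices and degenerate inputs

Problem sizes throughout (0.25-mm working resolution, 0.5/0.25/0.125-mm
convergence ladder, cohorts of a few hundred stones, 2000-replicate null
calibrations) are chosen to match the study's own scales. Other choices:
single-voxel masks have length 0 and an `NA` axis sentinel (width then
raises an invalid-axis error); fewer than four or coplanar points raise a
degenerate-geometry error in the hull; empty crops, sub-floor volumes
(no voxel ≥ 200 HU) and window levels above the volume maximum raise
descriptive errors rather than returning empty objects. All stochastic
components (phantom noise, readers, cohorts, permutation p-values) are
reproducible from integer seeds, and the caller's RNG state is restored.

## Known limitations

* The enclosing surface is convex: concavities of markedly lobulated
  stones are bridged, overestimating volume-by-hull and underestimating
  surface concavity. (The reported *volume* uses the voxel union and is
  unaffected.)
* No stone localisation: the ureteral position (upper/lower) and the ROI
  are inputs.
* The virtual reader is a bias+noise model on apparent size; it does not
  model caliper placement, zoom, or inter-slice selection.
* Phantoms are single convex stones; touching stones and phleboliths are
  out of scope.
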