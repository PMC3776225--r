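---
title: "Quantifying basal ganglia T2*w hypointensities: models, conventions, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying basal ganglia T2*w hypointensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bghypo)
```

## The problem

Multifocal hypointensities in the basal ganglia on T2\*-weighted MRI are
believed to mark mineralized lenticulostriate arterioles and perivascular
spaces. Their manual segmentation is slow and rater-dependent, so a pipeline
that turns rater masks plus standard structural channels into per-structure
statistics must pin down many small conventions — connectivity, overlap
rules, quantile types, normalizers — that publications rarely state fully.
This vignette records every such choice this package makes, why, and what the
synthetic test cohort can and cannot establish.

## Data model

All volumes are NIfTI-1, held as `voxel_grid` objects (3D array + voxel size
+ grid-to-world affine). The third array index enumerates axial planes — the
acquisition orientation of 2D T2\*w gradient-echo protocols, whose 2 mm
slices with 1×1 mm in-plane sampling motivate the default lattice. Masks are
strictly binary (files with other values are rejected, never thresholded) and
are written as unsigned 8-bit so write/read round trips are bitwise.
Intensities are 32-bit float; non-finite voxels are preserved and surfaced as
a QC count. A `subject_bundle` holds exactly three channels (T1w, T2w, and
T2\*w, spelled `T2sw` in code), the hypointensity/brain/tissue masks, and
subcortical masks keyed by FSL-FIRST codes (caudate 11/50, putamen 12/51,
pallidum 13/52) plus thalamus (10/49), which the internal-capsule derivation
consumes, and derived capsule codes 14/55.

## Intensity standardization

Raw scanner intensities are not comparable across subjects. The model is a
per-subject, per-channel linear map `s_std = α·s + β`, with (α, β) estimated
by ordinary least squares of the *reference* subject's robust tissue means on
the *subject's* robust tissue means over shared tissue classes. Two modes are
supported: the default two-point fit on {GM/WM, CSF} (matching a
four-class segmentation that merges gray and white matter) and a three-point
{GM, WM, CSF} mode. With two points the fit is exact, which yields a useful
invariant: re-fitting an already standardized subject returns α = 1, β = 0 to
machine precision.

Robust means are Huber M-estimators of location: ψ-function with tuning
constant c = 1.345 (95% efficiency at the Gaussian), scale fixed at
1.4826·MAD, iterated to |Δ| < 1e−8 (at most 100 iterations);
`MASS::huber()` performs the iteration. When the MAD is zero (more than half
the sample on one value) no MAD scale exists, so the estimator falls back to
the consistency-scaled mean absolute deviation about the median
(1.2533·mean|x − median|) with the same clipped-mean fixed-point iteration;
constant samples return the common value. Degenerate designs (identical
subject means across tissue classes) are refused rather than extrapolated.

Because the synthetic generator distorts each subject by a known affine map
`raw = a·true + b`, standardization against the undistorted reference is a
well-posed inversion: the fitted coefficients must approach `(1/a, −b/a)`.
The slope recovers to well under 2% relative error at the default noise
level. The intercept is judged on the intensity scale (reference GM/WM mean,
about 100 units) rather than relative to `−b/a`, which crosses zero; its
accuracy is set by the robust CSF mean, whose mixel-eroded mask is the
smallest sample in the fit.

## Structure masks

The internal capsule is approximated by dilating the globus pallidus mask
with a disk-shaped 2D kernel applied per axial slice and subtracting the
thalamus, pallidus and caudate masks. The radius is specified in world mm
(default 6) and converted per-axis to voxels, so the same physical kernel
applies at any in-plane resolution; the disk is rasterized by the
centre-distance test `dx² + dy² ≤ r²`. The putamen is deliberately not
subtracted; capsule voxels also claimed by any FIRST structure are ceded to
that structure before labeling, and the rare midline voxels reached by both
pallidal dilations go to the left capsule code. Intracranial volume is the
brain-mask volume; normal-appearing tissue is a structure mask minus the
hypointensity mask.

## Component labeling

Individual hypointensities are maximal six-connected (face-adjacent)
components, ordered deterministically by minimum linear voxel index. Each
component is labeled by maximal intersection with the structure masks under
a 50% rule: below 50% overlap with the union it is `outside` (kept, flagged,
excluded from burden/morphology/intensity stages); "at least 50%" is read
inclusively, so exactly half inside is labeled. An exact tie of the maximal
intersection is broken by the structure containing the component's minimum
standardized T2\*w voxel — standardized, not raw, so the rule is not
subject-scale dependent. If that voxel lies in none of the tied structures
(unspecified corner case), the lowest tied code is chosen with a warning.
Labeling is invariant to the order in which structure masks are supplied.

## Burden and morphology

Counts and loads are tabulated per structure code with left (11–14), right
(50–55) and whole-set aggregates; loads are `1e6·V/ICV` in ppm, so load
additivity across structures holds to 1e−9 ppm. Left/right differences in
count and load are tested with two-sided Wilcoxon rank-sum tests: exact null
distribution when the combined sample size is ≤ 20 and no ties, otherwise
the normal approximation with tie and continuity correction.

Morphology is computed per component. The number of occupied axial slices is
counted on the native grid, because the intra-slice (1 slice) vs inter-slice
(> 1) dichotomy is an acquisition property of 2 mm slices. All metric
computations then use a nearest-neighbour resampling to a 1 mm isotropic
lattice covering the component's bounding box plus one voxel, with a
round-half-up tie rule on the nearest-centre test. Volume is voxel count ×
1 mm³; maximum in-plane area is the largest per-slice voxel count × 1 mm².
Discrete compactness follows the enclosing-surface formulation
`C = (n − A/6)/(n − n^{2/3})` with `A` the number of exposed faces, clamped
to [0, 1] and defined as 1 for a single voxel; solid cubes attain the
maximum 1, and removing surface voxels strictly roughens (lowers) it.
Relative anisotropy comes from the eigenvalues of the voxel-centre
covariance (no per-voxel self-moment):
`RA = sqrt(Σ(λᵢ − λ̄)²)/(√3·λ̄)/√2`, i.e. the DTI-style RA renormalized by √2
to land in [0, 1]; equal eigenvalues (cubes, digital balls) give 0, a
one-voxel-wide straight segment gives exactly 1, and the measure is
invariant to 90° lattice rotations. Summaries report type-7 quartiles per
slice class plus rank-sum p-values between classes.

## Spatial probability mapping

Each subject's hypointensity mask is brought to the reference grid and
normalized into a spatial probability map; maps are averaged with equal
weights 1/k. Two conventions required a decision. First, the normalizer:
maps are divided by their sum, making each subject a proper probability
density and the aggregate a mixture; `normalize = FALSE` retains fractional
occupancy instead. Second, the warp convention: displacement fields live on
the reference grid and hold the world-mm displacement the subject's content
undergoes on its way into reference space, so the mask is sampled
trilinearly at `reference_world − d` and a pure translation `d` moves the
density centroid by exactly `+d`. Warp estimation itself (nonlinear
registration) is out of scope; identity warps are the synthetic default, so
the aggregation arithmetic is fully testable.

## Intensity statistics

All quantiles anywhere in the package are type-7 (linear interpolation
between order statistics); this single convention matters because threshold,
quartile and summary comparisons all depend on it. Per-structure
segmentation thresholds are the 97th percentile of standardized T2\*w
intensities inside the structure's hypointensity voxels, referenced to the
median of the structure's normal-appearing voxels as
`100·(1 − s_thresh/s_nabg)` percent below normal.

Cohort intensity distributions aggregate per-subject histograms on one
shared bin grid. The bin width minimizes the Shimazaki–Shinomoto cost
`C(Δ) = (2·mean(k) − var(k))/Δ²` (biased variance of bin counts) over a
100-point logarithmic grid between range/200 and range/2, with ties going to
the smaller width — bounds and tie-break are implementation choices; the
selection is scale-equivariant on the log grid. Subject densities are
normalized to unit integral and averaged with equal weights; quartiles are
read from the aggregated cumulative density by linear interpolation within
bins; Bowley skewness is `(Q1 − 2Q2 + Q3)/IQR`; modality is the number of
strict local maxima of the aggregated density after merging equal-valued
plateaus.

## Appearance classification

Per structure (hemispheres merged by default, per-hemisphere behind a flag)
and channel, the subject's pooled hypointensity voxels are compared with the
structure's normal-appearing voxels by a two-sided Mann–Whitney U test:
exact when the smaller sample has ≤ 8 observations and there are no ties,
otherwise normal approximation with tie and continuity correction. Only a
significant test (α = 0.05) with a darker/brighter median yields
hypo-/hyperintense; everything else is isointense (equal medians under
significance: isointense with a warning). The classification is invariant to
common positive affine rescaling of both samples.

One consequence worth stating: if a channel's lesion contrast is exactly
zero, the isointense rate equals one minus the realized type-I error of the
rank test. With the normal approximation at typical sample sizes (tens of
lesion voxels against a few hundred normal-appearing voxels) that error sits
at 4.5–5.7%, so iso rates marginally below 95% are expected behavior, not a
pipeline defect.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes, not
anatomy or MR physics. Geometry is ellipsoidal: a brain, two ventricular CSF
bodies, and eight deep nuclei (caudate, putamen, pallidum, thalamus × 2)
placed symmetrically, scaled to the field of view. The default grid is
128×128×64 voxels at 1×1×2 mm — an isotropic 128 mm world cube with 2 mm
axial slices. Lesions are spheres in world mm before rasterization
(components are reported as smooth and spherical), placed so that no two can
merge into one six-connected component.

Defaults and their rationale, fixed once:

* **Lesion plan.** Poisson counts per structure and hemisphere with means
  0.03 / 0.13 / 1.15 / 0.29 (caudate / putamen / pallidum / capsule per
  side): expected inside-count shares of roughly 72 / 18 / 8 / 2 percent for
  pallidum / capsule / putamen / caudate and about three lesions per subject
  overall, the pallidum-dominant pattern reported for community cohorts.
* **Lesion size.** Radii uniform on 0.9–2.2 mm, so the median sphere volume
  is near the reported 12 mm³ median component volume.
* **Contrast.** Normal-tissue T2\*w means order caudate (108) > putamen
  (104) > pallidum (93), with GM/WM at 100 and CSF at 150; T1w 120/40 and
  T2w 100/180 for brain/CSF give the usual tissue contrast. Lesion T2\*w
  intensities follow a reflected Weibull law, `base − Weibull(shape 1.5,
  scale 8)` below a dark base of 55 — negatively skewed, far below the
  normal-tissue 3rd percentile, so the default regime is separable and exact
  recovery is a meaningful test. Lesions are T1w-dark (−25) and T2w-neutral
  (0), the pallidal pattern.
* **Noise and distortion.** Gaussian noise SD 2 (≈ 2% of tissue intensity,
  a plausible post-correction SNR); per-subject affine intensity distortion
  with slope in (0.8, 1.2) and intercept in (−10, 10) — exactly the model
  class the standardization inverts. Bias fields default to zero amplitude
  because inputs are assumed bias-corrected.
* **Mixels.** A one-voxel six-neighbourhood shell is eroded off every tissue
  mask, emulating partial-volume exclusion.

Per-subject seeds derive deterministically from the master seed, so
generation is bitwise reproducible. Sample-level access to the generative
laws (`sample_lesion_intensity()`, `sample_tissue_intensity()`,
`sample_lesion_counts()`, `sample_lesion_radius()`) supports
distribution-shape and classification experiments at scale without
rasterizing volumes.

What the phantom does **not** model — realistic anatomy, T2\* decay and
blooming, motion or flow artifacts, rater variability in mask boundaries,
partial-volume lesion edges — bounds what green tests mean: they establish
that the pipeline's arithmetic, rules and estimators recover a known truth
under the stated assumptions, not that the pipeline segments or labels real
images with any particular accuracy.

## Problem sizes used by the test suite

Unit tests run a reduced phantom (96×96×48 voxels, 3/4-scale anatomy,
radii 0.8–1.8 mm) for speed. Recovery experiments use the full-size default
geometry: 20 subjects for standardization recovery, a 10-subject cohort for
the exact end-to-end recovery run, 100 replicates of 20 × 150 draws for the
negative-skew Bowley experiment, 20 replicates of 20 × 500 draws for the
symmetric control (500 draws keep the Bowley sampling noise well inside the
±0.05 band), and a 24-subject phantom for the appearance-pattern experiment.

## Known limitations

* The internal-capsule mask is a geometric proxy (dilation minus neighbours),
  not an anatomical segmentation; its value is consistency, not accuracy.
* Compactness maxima are attained by cubes, which is stricter than the
  intuitive "smooth and round" ideal; comparisons between components are
  unaffected, absolute values should not be read as sphericity.
* The aggregated-histogram quartiles are computed from binned densities, so
  they carry a discretization error of order the bin width; Bowley values
  within ± one bin-width/IQR of zero should not be over-interpreted.
* Whole-run caching is keyed on the configuration hash; editing inputs on
  disk without changing the configuration defeats it (`resume = FALSE`, the
  default, always recomputes).
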