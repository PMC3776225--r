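# bghypo

Quantitative characterization of multifocal T2\*-weighted (T2\*w)
hypointensities in the basal ganglia on conventional structural MRI.

Focal dark spots on T2\*w gradient-echo images of the basal ganglia are a
common finding in older adults and are thought to reflect mineralized small
vessels and perivascular spaces — a candidate imaging marker of cerebral
small vessel disease. `bghypo` turns a rater's binary hypointensity masks,
together with co-registered T1w/T2w/T2\*w volumes and subcortical
segmentations, into reproducible per-structure statistics: counts, loads,
shape descriptors, spatial probability maps, intensity-distribution
summaries, and multimodal appearance classes. A fully synthetic multi-channel
cohort generator with ground truth makes every stage testable without patient
data.

## The methods at the core

* **Intensity standardization.** Each subject's channel is mapped by
  `s_std = α·s + β`, where (α, β) come from regressing the reference
  subject's robust tissue means on the subject's robust tissue means across
  tissue classes (GM/WM and CSF by default). Robust means are Huber
  M-estimators of location (ψ-function with c = 1.345, scale fixed at
  1.4826·MAD). With two tissue classes the fit is exact, so standardizing an
  already-standardized subject is the identity map.
* **Component labeling.** Individual hypointensities are the six-connected
  components of the hypointensity mask. A component is assigned the structure
  code (FSL-FIRST caudate/putamen/pallidum codes 11/12/13 and 50/51/52, plus
  derived internal-capsule codes 14/55) with which it shares the most voxels,
  provided at least 50% of it lies inside the structure set; exact ties are
  broken by the structure containing the component's darkest standardized
  T2\*w voxel. Everything else is `outside` and excluded downstream.
* **Internal capsule proxy.** The globus pallidus mask is dilated slice-wise
  by a 6 mm world-space disk and the thalamus, pallidus and caudate masks are
  subtracted.
* **Burden.** Per-structure counts and loads, the latter as parts per million
  of intracranial volume (`1e6 · V / ICV`), with two-sided Wilcoxon rank-sum
  tests on left vs right hemisphere totals.
* **Morphology.** On a 1 mm isotropic nearest-neighbour resampling: volume,
  maximum in-plane area, discrete compactness
  `C = (n − A/6)/(n − n^{2/3})` (n voxels, A exposed faces; 1 for a cube),
  and relative anisotropy of the inertia eigenvalues (0 isotropic, 1 for a
  line), summarized by quartiles for intra-slice vs inter-slice components.
* **Spatial probability mapping.** Per-subject masks are warped to the
  reference grid, normalized to unit sum, and averaged with equal weights.
* **Intensity distributions.** Per-structure segmentation thresholds (97th
  percentile inside the hypointensity mask, referenced to the
  normal-appearing median), cohort-aggregated histograms with a
  Shimazaki–Shinomoto cost-optimal bin width, quartiles read from the
  aggregated density, and the Bowley skewness `(Q1 − 2Q2 + Q3)/IQR`.
* **Appearance.** A structure's hypointensities are hypo-/hyper-intense on
  T1w or T2w only if a Mann–Whitney U test against normal-appearing tissue is
  significant at α = 0.05 *and* the medians differ in that direction;
  otherwise isointense.

## Worked example

Simulate a 5-subject cohort and run the full pipeline:

```r
library(bghypo)
rep <- run_pipeline(list(out_dir = "demo",
                         simulate = list(n_subjects = 5, seed = 11)))
rep$fractions
#> # A tibble: 3 × 5
#>   region   location count total percent
#>   <chr>    <chr>    <int> <int>   <int>
#> 1 pallidum inside      14    19      74
#> 2 capsule  inside       4    19      21
#> 3 putamen  inside       1    19       5
glance(rep$histograms$T2sw)
#> # A tibble: 1 × 10
#>   channel width n_bins n_subjects   q25   q50   q75   iqr  bowley n_modes
#>   <chr>   <dbl>  <int>      <int> <dbl> <dbl> <dbl> <dbl>   <dbl>   <int>
#> 1 T2sw     4.44      8          5  45.1  48.7  51.6  6.49 -0.0984       2
rep$appearance
#> # A tibble: 4 × 6
#>   structure channel class     n n_subjects percent
#> 1 pallidum  T1w     hypo      5          5     100
#> 2 pallidum  T2w     iso       5          5     100
#> 3 putamen   T1w     hypo      1          1     100
#> 4 putamen   T2w     iso       1          1     100
```

Reading the output: 74% of the recovered components sit in the globus
pallidus (the generator's pallidum-dominant lesion plan), the cohort T2\*w
intensity distribution of the hypointensities is left-skewed
(Bowley −0.098 < 0, matching the generative reflected-Weibull law), and
pallidal hypointensities classify as dark on T1w but neutral on T2w — the
generated contrast pattern. `rep$recovery` compares every count, load and
label against the generator's ground truth; on this phantom all are exact.
Stage tables (burden, morphology, thresholds, histograms, appearance, QC) are
written as CSV under `out_dir`, the aggregate spatial map as NIfTI.

A thin CLI wrapper is installed at `inst/cli/bghypo.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bghypo.R", package = "bghypo"))')" all --config config.yaml
```

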