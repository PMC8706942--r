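---
title: "ROI-size stability of liver MRI radiomic features: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-size stability of liver MRI radiomic features: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiomic features — quantitative summaries of the intensity distribution
and spatial texture inside a region of interest (ROI) — are only useful for
cross-study modelling if they measure tissue, not geometry. When the same
healthy liver parenchyma is measured through spherical 3D ROIs of 10, 20
and 30 mm diameter, many features shift systematically with the ROI
diameter: their value is *volume-confounded*. `roistab` implements the full
analysis that separates size-robust features from volume-confounded ones:

1. simulate a cohort of liver-parenchyma volumes on three scanner
   geometries and two pulse-sequence contrasts (T1w, T2w);
2. place concentric spherical ROIs of 10/20/30 mm in each volume;
3. extract 93 IBSI-style features per ROI (18 first-order, 24 GLCM,
   14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM);
4. per scanner and sequence, test each feature across ROI sizes with
   pairwise Mann–Whitney U tests (Bonferroni within the three size pairs)
   and quantify agreement with overall concordance correlation
   coefficients (OCCC) over the size sets {10, 20, 30} and {20, 30} mm;
5. report the features that are *concordantly* robust on every scanner.

```{r, eval = FALSE}
library(roistab)
res <- run_study()           # default study configuration, fixed seed
res$summary$T1w$robust_intersection
```

## The synthetic cohort

Clinical liver MRI of the kind this analysis targets is not publicly
shareable, so the cohort module generates volumes with exactly the
statistical structure the analysis assumes, and nothing more:

* **Stationary correlated texture.** Each volume is white Gaussian noise
  smoothed by an isotropic (in mm) Gaussian kernel of scale
  `correlation_length`, rescaled so the marginal voxel SD equals
  `noise_sd` exactly. Smoothing uses circular boundaries, which makes the
  field strictly stationary: the *expected* mean, median, RMS and
  percentiles of an ROI then do not depend on the ROI's size or position —
  the mechanism behind size-robust first-order features. Binned texture
  statistics, by contrast, still shift with ROI size because the number of
  voxels, runs and zones grows with the ROI.
* **Subject-level variation.** A per-volume mean offset is drawn from
  `Normal(mean_intensity, subject_sd)`, independently per sequence. This
  between-subject spread is what the OCCC measures agreement against.
* **Scanner geometry.** The six `default_profiles()` carry the emulated
  acquisition geometry: 1.125 × 1.125 mm in-plane with 5.5 mm slice
  spacing on both 3 T scanners, and 1.09375 mm (T1w) or 1.3671875 mm
  (T2w) in-plane with 6.6 mm slice spacing at 1.5 T. The strong anisotropy
  is deliberate: a 10 mm sphere spans a single slice, which is precisely
  the regime in which small-ROI behaviour matters.

Default intensity parameters (all config-overridable): T1w mean 350 and
T2w mean 180 arbitrary units, `subject_sd` = 10% of the mean, `noise_sd` =
8% of the mean, `correlation_length` = 2 mm. The absolute magnitudes are
immaterial — the pairwise tests are rank-based and the OCCC is scale-free —
only the ratio of between-subject spread to within-ROI noise and the
correlation scale drive the results. The values were fixed once as a
plausible abdominal-MRI regime (≈12:1 signal-to-noise, texture correlation
of a couple of voxels in-plane). True per-scanner parenchymal signal/noise
statistics are unknown; these defaults are documented placeholders.

The generator deliberately does **not** model MR physics (no TR/TE/flip
angle signal equations), bias fields, breathing motion, vessels or bile
ducts (the emulated protocol excludes them from ROIs anyway), or
fat/iron signal alterations. Consequently, passing tests show that the
*pipeline* reproduces the size-robustness mechanism on data satisfying its
assumptions; they do not certify numerical agreement with any clinical
feature table, which would require the original images.

Cohort sizes default to 25/19/22 subjects on the three scanners (66
subjects, 132 volumes with both sequences), matching the emulated study's
scale so that the power of the group-size-driven tests is comparable.
Per-volume seeds are derived from one master seed by a stable hash of
(subject, scanner, sequence), so any volume can be regenerated in
isolation.

## ROI geometry

ROIs are spheres defined in physical millimetres. A voxel belongs to the
mask iff its centre lies within `diameter/2` of the sphere centre
(boundary ties included) — the simplest deterministic inclusion rule;
partial-volume weighting is out of scope. Index-space ("voxel radius")
spheres would be badly wrong here because slice spacing is ≈5× the
in-plane spacing. The default placement rule puts the centre at the
volume's physical centroid snapped to the nearest voxel centre; the rule
is diameter-free, so the three study sizes share one centre per volume
(identical placement across sizes), and centres are recomputed per
sequence volume rather than copied between sequences. The drawing tool
convention of the emulated workflow (voxel-centre vs any-overlap
inclusion) is unknown; the voxel-centre rule is the documented choice.

## Feature extraction conventions

* **Discretization**: fixed bin width (default 25 signal units), with the
  anchor at `bin_width * floor(min/bin_width)` so bin edges align across
  ROI sizes and the levels are invariant under whole-bin shifts. A
  consequence worth knowing: a near-constant sample whose values straddle
  a bin edge legitimately occupies two bins.
* **Neighbourhoods**: distance 1 in index space over the 26-neighbourhood,
  with 13 unique directions for GLCM/GLRLM. Index-space neighbourhoods on
  an anisotropic grid are the convention of the standard radiomics
  toolchain; mm-aware neighbourhoods are a non-goal. Masked-out voxels are
  excluded from every neighbourhood computation.
* **Aggregation**: GLCM and GLRLM features are computed per direction and
  averaged over directions; directions with no voxel pair (through-plane
  offsets in a single-slice 10 mm ROI) are skipped rather than averaged
  in as zeros.
* **No resampling**: features are computed on the native anisotropic grid;
  the physical voxel volume enters only total energy.
* **Degenerate conventions** (single-level ROIs are possible on smooth
  synthetic data): GLCM correlation := 1, MCC := 1, IMC2 := 0, NGTDM
  contrast := 0, first-order skewness/kurtosis := 0, uniformity := 1.
  Each is asserted by a test.
* **Percentiles/median**: linear interpolation between order statistics
  (`quantile` type 7), the ubiquitous default — documented because the
  median and percentiles are headline robust features.
* GLDM dependence counts include the centre voxel (smallest dependence
  size is 1), keeping the `1/j²` emphases defined; the dependence
  tolerance is `alpha = 0`.

Every texture matrix builder is verified against an independent
brute-force per-voxel oracle on hundreds of random masked arrays, along
with the mass-conservation identities (runs: Σ count×length = N per
direction; zones: Σ count×size = N; dependence: Σ count = N).

## Statistics

* **Mann–Whitney U**: two-sided, unpaired — unpaired even though size
  groups share subjects, for fidelity to the emulated design. Exact
  enumeration when both groups have ≤ 8 observations without ties,
  otherwise the continuity- and tie-corrected normal approximation.
  (Exhaustive enumeration over every attainable U shows the two routes
  agree within 0.05 for group sizes 3–8; at size 2 the approximation can
  deviate by 0.09, one reason the analysis requires n ≥ 3 per group.)
* **Bonferroni family**: the three size pairs within one
  feature/scanner/sequence (factor 3, configurable). The correction is not
  spread across the 93 features; the family is the set of pairwise size
  comparisons asked about one feature.
* **OCCC**: Barnhart's overall CCC in moment form with 1/n divisors
  (Lin's original convention; a 1/(n−1) switch is provided since the
  choice slightly moves the estimate at small n). For two groups it
  reduces exactly to Lin's CCC, which an independently coded oracle
  confirms to 1e-12. Agreement ≥ 0.90 is flagged "excellent". When every
  group is constant and equal the estimator is 0/0; such cells are flagged
  degenerate rather than silently NaN. No confidence intervals are
  reported — point estimates only.
* **Concordance across scanners**: a feature is robust for a sequence only
  if its flags hold on *every* scanner (intersection semantics), for both
  the nonsignificance criterion and each OCCC subset.

## Problem sizes and determinism

The default study simulates 132 volumes of 48 × 48 × 12 voxels and
extracts 396 ROIs (three diameters per volume), which completes in well
under a minute on a laptop-class core; the property suites use ≤ 5 × 5 × 3
arrays where brute-force oracles are exact and cheap. Everything is
deterministic given the master seed: rerunning `run_study()` with one
configuration reproduces every output file byte-for-byte.

## Known limitations

* The synthetic cohort reproduces the *qualitative* pattern (which
  features are robust and which are volume-confounded), not any clinical
  table of p-values or OCCCs — those depend on unshared images.
* Under the default noise calibration the **median's** concordance over
  the full 10–30 mm range sits near the 0.90 excellence threshold: the
  sample median's variance is ≈ π/2 times the mean's, and a 10 mm ROI on
  these grids is a single slice of ~40–75 voxels with few independent
  texture patches, so `occc_10_30` for the median lands in the 0.84–0.91
  band depending on the draw, while mean and RMS sit comfortably above
  0.90. The mean/median/RMS trio is always nonsignificant in the pairwise
  tests, and energy/total energy always fail both criteria.
* Feature mathematics follow one toolchain dialect (fixed-bin-width
  discretization, per-direction averaging, index-space neighbourhoods);
  alternative dialects (merged-matrix aggregation, resampled grids) would
  move texture feature values and are exposed only where noted.
* No shape features (ROI sizes vary by design), no filtered-image
  features, no DICOM ingestion.
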