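---
title: "Methods: a digital phantom for radiomic feature stability under varying PET reconstruction settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital phantom radiomic stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

PET radiomic features are sensitive to the image reconstruction protocol:
the same acquisition reconstructed with different OSEM subset/iteration
counts, with or without time-of-flight (TOF), or with a different
post-reconstruction Gaussian filter yields different texture values. A
feature is only useful as a biomarker if it is (a) *stable* against such
protocol changes and (b) still *sensitive* to the biology it is meant to
capture — here, the spatial heterogeneity of tracer uptake. `radstab`
reproduces this trade-off study entirely in software, on a digital
phantom whose ground truth is known exactly, so every stage is
deterministic given a seed and auditable.

## The phantom

The phantom is a water cylinder (default radius 100 mm, length 120 mm) at
5 kBq/ml background activity, with four tumour-mimicking inserts mounted
90 degrees apart around the axis. Each insert bundles 7 parallel
syringes: one central, six on a 38 mm pitch-circle. We use syringe radius
9.5 mm and length 73 mm, for two reasons: 9.5 mm is the unique radius at
which the six ring syringes exactly touch the central one on a 38 mm
pitch circle (hexagonal close packing, as in a physical syringe bundle —
any larger radius would overlap), and the length then brings the insert
volume to `7 * pi * 9.5^2 * 73 = 144.9` cm³, matching the ~145 cm³
tumour model. The four canonical fillings are:

| shape | filling | model |
|---|---|---|
| 1 | 7 × 40 kBq/ml | homogeneous tumour |
| 2 | 6 × 40, central cold | homogeneous, necrotic core |
| 3 | centre 40, ring alternating 80/20 | heterogeneous (max:min 4:1) |
| 4 | as 3, central cold | heterogeneous, necrotic core |

Three details the physical experiment leaves open are fixed here as
explicit configuration, not as inferences: the necrotic syringe is
water-filled (imaged at background activity), the heterogeneous spatial
arrangement is centre-40 / ring-alternating-80-20, and the necrotic
variants omit the *central* syringe. All three are parameters of
`insert_config()` and can be overridden.

Voxelization uses a centre-point rule on an isotropic grid (default 2 mm;
the 200 mm field of view then gives a 100×100×60 grid): a voxel belongs
to a syringe iff its centre is inside the cylinder. There is no
partial-volume subsampling; at 2 mm the discretized insert volume is
within a few percent of the analytic one, and the activity-conservation
test bounds the error at ±10%. The region of interest is the union of the
7 syringe cylinders — the homogeneous insert's footprint — translated to
each mounting position, mirroring a single ground-truth contour overlaid
on every configuration so that delineation contributes no variance.

## The reconstruction surrogate

True list-mode OSEM reconstruction is out of scope; `radstab` models its
image-domain consequences with a four-step chain
(`emulate_reconstruction()`):

1. **Intrinsic resolution**: Gaussian blur of FWHM `psf_fwhm` (default
   5 mm, a typical whole-body PET point-spread width).
2. **Iteration noise**: additive zero-mean Gaussian noise with standard
   deviation `base_sd * sqrt(subsets * iterations / 48)`. OSEM noise
   grows with the effective update count (the subset × iteration
   product), and 48 = 24 × 2 is the default product; `base_sd` defaults
   to 0.5 kBq/ml, i.e. 10% of the water background.
3. **TOF gain**: when TOF is on, the noise SD is divided by 1.35,
   reflecting the SNR benefit of time-of-flight localization.
4. **Post-filter**: Gaussian blur with the setting's cut-off FWHM
   (0–7 mm; 0 = none), then clipping at zero.

All four constants live in `noise_model()` and are deliberately simple:
the surrogate is not meant to predict absolute feature values of any
scanner, only to reproduce the *structure* of the problem — noise that
rises with the update product, a noise-reducing TOF flag, and a
resolution-degrading filter sweep. Gaussian blurs are separable with
edge-renormalized truncated kernels (flat regions stay flat), and each
setting's noise is drawn under a seed derived deterministically from the
run seed, so the full 21-image study is a pure function of
(config, seed).

The 21 settings are one-at-a-time variations around the clinical default
(24 subsets, 2 iterations, 6.4 mm, TOF on): 5 subset values, 6 iteration
values, 8 filter values, 2 TOF states. Note that three families contain
the default value of their own parameter (24 subsets, 2 iterations, TOF
on), so those settings coincide with the default image in expectation and
only differ by their noise realization.

## Feature extraction

Intensities inside the ROI are discretized and five texture-matrix
families are computed (`extract_all()`, 78 features):

* **GLCM** (25): pair counts at Chebyshev distance 1, merged over all 13
  unique 3D directions into one symmetric matrix ("3D merged"
  aggregation).
* **GLRLM** (16): maximal same-level runs, merged over the 13 directions;
  run percentage divides the run count by voxels × directions.
* **GLSZM** (16): 26-connected equal-level zones (labelled as graph
  components via `igraph`).
* **GLDZM** (16): the same zones tabulated against the minimum city-block
  distance to the first out-of-ROI voxel (border voxels at distance 1).
* **NGTDM** (5): per-level summed deviation from the mean of the valid
  26-neighbours, with the usual degenerate-denominator conventions
  (coarseness capped at 1e6; contrast/busyness/complexity/strength 0 when
  a single grey level occupies the ROI).

Entropies use log base 2. Inputs whose spacing differs from the 2 mm
analysis grid are resampled first (trilinear for volumes, nearest
neighbour for masks). Every matrix builder is validated in the test suite
against an independent brute-force oracle (explicit pair/run/flood-fill
enumeration) on randomized small ROIs.

### Discretization: fixed bin number versus fixed bin size

The default is fixed bin number (FBN), `Ng = 64` over the in-ROI min–max
range, which makes features invariant to positive affine intensity
rescaling. FBN has a consequence worth understanding: in a *narrow-range*
region (the homogeneous insert, whose in-ROI spread is mostly noise and
edge falloff), the 64 bins resolve the noise itself, so local texture
measures such as GLCM dissimilarity can come out *higher* than in the
wide-range heterogeneous insert, where a level step corresponds to a much
larger activity difference. The regions remain consistently separated —
which is all the rank-based Friedman stage uses — but the *direction* of
naive "heterogeneous is rougher" intuitions is only guaranteed when level
differences keep their meaning in intensity units. For that reason a
fixed-bin-size mode (`discretize_fbs()`,
`extraction_params(discretization = "fbs", bin_width = 1)`) is provided,
under which the heterogeneous insert is indeed the rougher one; both
behaviours are asserted in the tests. FBN remains the default because it
needs no intensity calibration and is the common choice when absolute
scaling is untrusted.

## Stability analysis

For each feature and insert, the coefficient of variation
`COV = 100 * sd / |mean|` (sample SD) is computed within each setting
family and overall. Two overall modes exist: the mean of the four family
COVs (default — it weighs each varied parameter equally regardless of how
many levels it was tested at) and the COV pooled over all 21 settings.
Features whose mean is within `1e-12` of zero relative to their scale get
an undefined COV and are excluded from categorization but reported. The
four categories use thresholds 5/10/20% with boundaries inclusive on the
more stable side (a COV of exactly 5% is stable). The run report
categorizes each feature by its overall COV averaged over the four
inserts, and also keeps the per-insert tables.

## Distinguishability analysis

For each stable feature and each of the 6 insert pairs, the feature
values across the 21 settings form a 21×2 table; within each row the two
regions are ranked (midranks on ties) and

$$Q = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1), \qquad n = 21,\; k = 2.$$

The p-value uses the chi-square tail with k − 1 = 1 degrees of freedom by
default. Because the chi-square approximation is coarse for k = 2, an
exact mode is provided: with two columns, each untied row independently
favours either region under the null, so |R₁ − R₂| follows a folded
binomial and the exact p is the two-sided sign-test tail (tied rows drop
out). The exact mode is slightly more conservative (at n = 21 it needs 16
rather than 15 one-sided wins for p < 0.05); the default follows the
common chi-square convention. No multiple-testing correction is applied —
the selection rule is deliberately the fixed per-pair α = 0.05 with the
all-6-pairs conjunction, which is itself a strong filter.

## What the synthetic study does and does not show

The generator reproduces the *design* of the physical experiment —
activities, geometry, setting grid, single-contour ROI — but not the
physics of any scanner: there is no attenuation, scatter, randoms or
sinogram-domain coupling, the noise is Gaussian and spatially white
before filtering rather than reconstruction-correlated, and contouring on
the digital phantom is exact. Consequently the pipeline's headline counts
(how many features are stable, how many distinguishable) characterize the
surrogate conditions, not any scanner; they are expected to agree with
physical studies qualitatively — smoothing is the dominant source of
feature variation, TOF the smallest; stable-and-distinguishable features
concentrate in GLCM difference-type statistics — but not numerically.
Tests that depend on noise are run over ≥20 seeded replicates and assert
qualitative orderings or frequencies, never exact values.

## Numerical choices and degenerate inputs

* Blur kernels truncate at 3σ and are renormalized per voxel at edges.
* A constant ROI discretizes to a single level and is flagged degenerate;
  single-cell GLCMs give joint maximum 1 and zero contrast; GLCM
  correlation and the first information-correlation measure are defined
  as 0 when their variance/entropy denominators vanish.
* An ROI with no valid voxel pair at the GLCM distance is an error, as is
  an empty mask, a negative filter FWHM, or mismatched volume/mask grids.
* Zone labelling is 26-connected; the GLDZM border distance is the
  free-space city-block distance to the nearest out-of-ROI voxel, with
  the volume treated as surrounded by out-of-ROI space.
* Random-number use is confined to `emulate_reconstruction()`, which
  seeds locally and restores the caller's RNG state.

## Problem sizes

The package's own studies use the 2 mm grid (100×100×60 voxels, ~18,200
ROI voxels per insert) for production runs — the full 4-insert ×
21-setting pipeline takes ~30 s on one CPU — and a 4 mm grid for
demonstration and most unit tests, which exercises identical code paths
at a fraction of the cost. The stochastic end-to-end property (GLCM
dissimilarity separating homogeneous from heterogeneous pairs at α = 0.05
across the setting grid) is asserted over 20 replicates at the 2 mm
default conditions.

## Known limitations

* The reconstruction surrogate is image-space only; it cannot reproduce
  convergence-dependent bias, Gibbs ringing from PSF modelling, or
  spatially varying noise correlations.
* The COV-category thresholds (5/10/20%) and α = 0.05 are conventions,
  exposed as parameters.
* GLDZM distances use the free-space city-block metric, which can differ
  from a geodesic in-mask metric for strongly non-convex ROIs.
* Exact Friedman p-values are implemented for the two-region case only.
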