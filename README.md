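# radstab

Radiomic texture features promise quantitative biomarkers from PET images,
but their values shift when the same scan is reconstructed with different
settings — a core obstacle for multi-centre studies. `radstab` is an R
package for asking, on a fully controlled digital phantom, two questions
about each of 78 three-dimensional texture features:

1. **Is it stable?** How much does the feature move when the
   reconstruction settings (OSEM subsets, iterations, time-of-flight,
   Gaussian post-filter width) change?
2. **Is it still useful?** Among the stable features, which ones can still
   statistically separate homogeneous from heterogeneous uptake regions?

The package targets physicists and image-analysis researchers who want a
reproducible, scanner-free testbed for feature-robustness questions, and
it reads user-supplied NIfTI volumes and masks so the same feature and
statistics machinery can be applied to real images.

## What it computes

**Phantom.** A water cylinder (5 kBq/ml background) carries four tumour
inserts, each a bundle of 7 syringes (38 mm pitch-circle diameter,
~145 cm³ per insert): shape 1 homogeneous (7 × 40 kBq/ml), shape 2
homogeneous with a cold necrotic core, shape 3 heterogeneous (20/40/80
kBq/ml, max:min = 4:1), shape 4 heterogeneous with a necrotic core.
A single ground-truth ROI (the shape-1 syringe footprint) is overlaid on
every insert position, removing delineation variability.

**Reconstruction surrogate.** List-mode OSEM is replaced by a documented
image-space chain: intrinsic Gaussian PSF blur, additive Gaussian noise
with standard deviation proportional to `sqrt(subsets x iterations)`
(divided by a TOF gain when TOF is on), then the Gaussian post-filter of
the setting's cut-off FWHM. The 21 settings are one-at-a-time variations
around the clinical default (24 subsets, 2 iterations, 6.4 mm filter,
TOF on): subsets {12,16,18,24,32}, iterations {1..6}, filter {0..7} mm,
TOF {on,off}.

**Features.** 78 IBSI-style 3D features — 25 GLCM, 16 GLRLM, 16 GLSZM,
16 GLDZM, 5 NGTDM — from matrices merged over the 13 unique 3D directions
at distance 1, after fixed-bin-number discretization (Ng = 64; a
fixed-bin-size mode is also provided).

**Stability.** Per feature, the coefficient of variation
`COV = 100 * sd / |mean|` across each setting family and overall, binned
into four categories: stable (COV ≤ 5%), moderately stable (5–10%],
poorly stable (10–20%], unstable (> 20%).

**Distinguishability.** For each stable feature and each of the
`C(4,2) = 6` insert pairs, a Friedman rank test across the n = 21
settings (k = 2 regions):

```
Q = 12 / (n k (k+1)) * sum_j R_j^2  -  3 n (k+1)
```

with `R_j` the column rank sums; p from the chi-square tail with k − 1
degrees of freedom (an exact sign-permutation mode is available for
k = 2). A feature is *distinguishable* iff p < 0.05 for all 6 pairs.

## Worked example

A complete run on a coarse 4 mm demonstration grid (a production run at
the default 2 mm grid takes under a minute):

```r
library(radstab)
cfg <- default_run_config(geometry = phantom_geometry(voxel_spacing = 4),
                          seed = 42)
report <- run_pipeline(cfg)
print(report)
#> radstab run report
#>   78 features x 4 shapes x 21 settings
#>   stability: 40 stable, 18 moderately stable, 13 poorly stable, 7 unstable
#>   distinguishable (all 6 pairs, alpha-significant): 29 of 40 stable
#>     glcm_joint_variance, glcm_difference_average, glcm_difference_entropy, ...
```

The report says: of the 78 features extracted from all 4 inserts under
all 21 reconstruction settings, 40 kept an overall COV at or below 5%
(stable), and 29 of those also differed significantly (Friedman,
p < 0.05) between *every* pair of insert configurations — features that
are simultaneously robust to the reconstruction and sensitive to uptake
heterogeneity. Per-feature detail is in the returned tables:

```r
head(report$stability_overall)
#>                    feature cov_overall          category
#> 1       glcm_joint_maximum  18.2546203     poorly_stable
#> 2       glcm_joint_average   0.6780532            stable
#> 3      glcm_joint_variance   3.1699440            stable
#> 4       glcm_joint_entropy   1.7258959            stable
#> 5  glcm_difference_average   1.2909624            stable
#> 6 glcm_difference_variance   5.5423283 moderately_stable
```

`run_pipeline(cfg, outdir = "out")` additionally writes `features.csv`
(one row per feature, shape and setting), per-shape and overall stability
CSVs, the Friedman test table and a JSON report; `write_nifti = TRUE`
also saves every emulated volume and the ROI masks. Individual stages are
exported too: `build_phantom()`, `emulate_reconstruction()`,
`extract_all()`, `stability_table()`, `select_distinguishable()`.

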