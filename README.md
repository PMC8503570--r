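# cordsim

Simulation-based power analysis for spinal cord atrophy measured by
cross-sectional area (CSA).

Spinal cord atrophy is a biomarker of neurodegeneration in multiple
sclerosis, spinal cord injury and ALS, and is usually quantified as the cord
CSA on axial MRI slices, averaged between vertebral levels C3 and C5. Before
committing a clinical study to this outcome, two questions must be answered:
how precisely can a pipeline recover a *known* amount of atrophy, and how
many subjects are needed to detect a given atrophy against the measured
intra- and inter-subject variability? `cordsim` answers both at desk scale,
entirely from synthetic data:

* **Phantom cohorts** — curved-tube cord phantoms with a CSF sheath,
  T1w-like or T2w-like contrast polarity, additive Gaussian noise,
  per-slice vertebral-level labels, and analytically known CSA
  (`generate_phantom()`, `generate_cohort()`). Between-subject radii are
  drawn so the true-CSA coefficient of variation hits a target (default
  10%).
* **Atrophy + scan–rescan simulation** — atrophy is a homothetic (isotropic)
  scaling by `r`, shrinking every cross-section by `r²`
  (`atrophy % = 100·(1 − r²)`); scan–rescan repositioning is a random rigid
  transform (rotations ±2.5°, translations ±5 voxels, 30 Monte Carlo draws
  by default). Both are composed into a *single* affine so the image is
  interpolated only once (5th-order B-spline), and every draw is frozen to
  CSV for exact replay (`scaling_transform()`, `sample_rigid()`,
  `compose_transform()`, `resample()`, `freeze_transforms()`).
* **CSA measurement** — a deterministic reference segmenter for phantoms
  (histogram-mode midpoint thresholding, per-slice largest component,
  hole filling; `segment_reference()`, with a plug-in contract for external
  segmenters), per-slice pixel-count areas, a smoothing-spline centerline
  with slice-wise cosine angle correction `A_perp = A_axial · cos θ`, and
  averaging over C3–C5 included (`compute_csa()`).
* **Statistics** — intra-subject (scan–rescan) and inter-subject
  variability, the CSA error relative to the theoretical `r²` law, and
  minimum sample sizes

  ```
  n_unpaired = ⌈ (z_{α/2} + z_β)² (σ²_scaled + σ²_unscaled) / Δ² ⌉   (per arm)
  n_paired   = ⌈ (z_{α/2} + z_β)² σ²_diff / Δ² ⌉
  ```

  with `Δ = μ·(1 − r²)`, plus a 500-iteration Monte Carlo procedure that
  draws one transform per subject per iteration to estimate the sample-size
  variability (`cohort_stats()`, `csa_error()`, `sample_size_unpaired()`,
  `sample_size_paired()`, `monte_carlo_sample_size()`).

`run_pipeline()` orchestrates the full subjects × scalings × transforms
grid and `make_report()` lays the results out as wide per-atrophy tables.
A thin CLI (`inst/cli/cordsim`) exposes the same stages as shell
subcommands.

## Worked example

Eight T2w-like phantom subjects on a 0.8 mm grid, one simulated atrophy of
9.75 % (r = 0.95), five scan–rescan draws each:

```r
library(cordsim)
cfg <- run_config(n_subjects = 8, contrasts = "t2",
                  grid_shape = c(44L, 44L, 48L),
                  scalings = c(1, 0.95), n_transforms = 5,
                  mc_iterations = 100, powers = c(0.8, 0.9), seed = 42)
bundle <- run_pipeline(cfg)
dplyr::select(bundle$stats, scaling_r, atrophy_percent, grand_mean_mm2,
              mean_cov_t_percent, cov_s_percent)
#>   scaling_r atrophy_percent grand_mean_mm2 mean_cov_t_percent cov_s_percent
#> 1      0.95            9.75           60.4              2.13           12.5
#> 2      1               0              67.1              0.486          12.2
```

The unscaled intra-subject COV of 0.49 % is the simulated scan–rescan
precision; the inter-subject COV of ~12 % reflects this particular
8-subject draw from a 10 %-COV cohort. The Monte Carlo sample sizes that
follow from these measurements:

```r
dplyr::select(bundle$sample_sizes, design, power, atrophy_percent, n, mc_mean, mc_sd)
#>   design   power atrophy_percent     n mc_mean mc_sd
#> 1 unpaired   0.8            9.75    24   23.6  1.01
#> 2 unpaired   0.9            9.75    31   31.3  1.40
#> 3 paired     0.8            9.75     1    1.02 0.141
#> 4 paired     0.9            9.75     1    1.13 0.338
```

i.e. about 24 subjects per arm detect a 9.75 % atrophy cross-sectionally at
80 % power with this cohort's variability, while a paired (longitudinal)
design needs almost none at so large an effect — which is why the paired
design is exercised at much smaller atrophies (`paired_scalings()`,
0.40–1.59 %).

The closed-form calculator works directly from published variability
numbers as well — with an inter-subject SD of 7.59 mm² per arm and a 10 %
atrophy of a 69.7 mm² cord (Δ = 6.97 mm²):

```r
sample_size_unpaired(7.59, 7.59, 6.97, alpha = 0.05, power = 0.90)
#> <sample_size_result> unpaired design, alpha = 0.05, power = 90%
#>   sigma_scaled = 7.59, sigma_unscaled = 7.59 mm^2
#>   Delta_group = 6.97 mm^2
#>   n = 25 per arm (50 total)
```

## Conventions

Voxel indices are 0-based in all CSV outputs; world coordinates are mm;
the axial slice index runs along the third array axis; voxel grids are
isotropic (1.0 mm "T1w-like", 0.8 mm "T2w-like" by default). Volumes and
masks are read and written as NIfTI-1.
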