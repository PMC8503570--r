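---
title: "Simulating detectable spinal cord atrophy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating detectable spinal cord atrophy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models behind `cordsim`, the parameters that
matter, and the design decisions taken where more than one reasonable
implementation existed. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The measurement model

The package treats spinal-cord atrophy quantification as a chain of four
models.

**Geometry.** A cord is a tube of radius $R(z)$ following a smooth
centerline $(c_x(z), c_y(z))$, wrapped in a CSF sheath and embedded in
background. Each axial slice of the phantom is the axial cut of the *local
cylinder*: an ellipse with semi-axes $R/\cos\theta$ (along the in-plane
projection of the tangent) and $R$ (across it), where $\theta(z)$ is the
angle between the centerline tangent and the slice normal. The axial-plane
area is therefore $\pi R^2/\cos\theta$ while the anatomically meaningful
perpendicular cross-section is $\pi R^2$ — exactly the bias that slice-wise
cosine correction removes. This makes the angle-correction test analytic: a
straight tube tilted by $\theta$ must show an uncorrected area ratio of
$1/\cos\theta$ and a corrected ratio of 1.

**Atrophy.** Tissue loss is modeled as a homothetic scaling of the whole
anatomy by $r \in (0, 1]$ about the grid center. Any plane figure scales by
$r^2$, so the implied atrophy is $100(1 - r^2)$ percent. An x-y-only
scaling would seem more anatomically plausible, but its apparent axial area
depends on the centerline angle
($A \cdot r\sqrt{r^2\cos^2\theta + \sin^2\theta}$, see
`xy_scaled_area()`), coupling the simulated effect size to each subject's
curvature; isotropic scaling avoids that coupling.

**Scan–rescan.** Repositioning between scans is a random rigid transform
with rotations uniform in ±2.5° per axis (intrinsic x-y-z Euler
convention) and translations uniform in ±5 voxels per axis — continuous
draws, converted to mm at apply time, so ±5 voxels means different
millimetres on the 1.0 mm and 0.8 mm grids. The rigid transform and the
atrophy scaling are composed into a single affine (`rigid ∘ scaling`:
shrink the anatomy, then reposition the subject) and the image is
resampled once, minimizing interpolation error. Rotations preserve area,
so the composition order cannot affect CSA statistics; the choice is
recorded in each transform's provenance along with the common
rotation/scaling center (the grid center — the natural fixed point when no
anatomical landmark exists).

**Measurement.** Segmentation of a phantom is a deterministic three-mode
intensity model: background, cord and CSF modes are estimated from the
intensity density and the cord is thresholded at the midpoint between the
cord and CSF modes (above it for T1w-like polarity, between the
background/cord and cord/CSF midpoints for T2w-like), then reduced to the
largest 4-connected component per slice with holes filled. The midpoint of
two plateau values lands on the half-intensity crossing of a smoothed
edge, which is the sub-voxel boundary of the object — this is what makes
the segmenter consistent between raw and resampled volumes. CSA is the
per-slice pixel count times the pixel area, corrected by
$\cos\theta$ along a spline-regularized centerline, and averaged over all
slices labeled C3–C5 (closed range).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| mean cord CSA | 70 | mm² | order of the healthy human cervical cord |
| between-subject CSA COV | 10 | % | matches the spread reported across healthy adults |
| voxel size | 1.0 (t1) / 0.8 (t2) | mm | the two native isotropic grids the pipeline emulates |
| CSF rim | 3 | mm | typical subarachnoid space around the cervical cord |
| rigid bounds | ±2.5 / ±5 | ° / voxels | plausible inter-session repositioning |
| transforms per subject | 30 | – | scan–rescan Monte Carlo sample size |
| interpolation order | 5 | – | high-order B-spline, one resampling |
| α, powers | 0.05, {0.80, 0.90} | – | conventional two-sided test levels |
| Monte Carlo iterations | 500 | – | sample-size variability estimate |
| unpaired scaling grid | 1.0–0.93 | – | atrophies 1.99–13.51 % |
| paired scaling grid | 1.0–0.992 | – | atrophies 0.40–1.59 % |

Cohort radii are Gaussian with $\sigma_R = \bar R \cdot \mathrm{COV}/200$;
since CSA $\propto R^2$, the CSA COV is twice the radius COV to first
order, and at a 10 % CSA COV the second-order error is ~0.25 % — far below
the sampling error of any cohort size used here. The distribution shape is
a modeling choice (nothing in the emulated study constrains it); it is
configurable through `cohort_specs()`.

The default cohort centerline is a gentle sinusoid (amplitude 1.5 mm,
period 60 mm, peak angle ≈ 9°), emulating cervical lordotic curvature.
Curvature also varies the cord's sub-voxel position across slices, which
makes slice-averaged areas far less sensitive to how the cord happens to
sit on the voxel lattice — straight, lattice-aligned cords are a worst
case that real anatomy never presents.

## Numerical choices

**Resampling.** Orders 0/1/3/5 are supported; orders ≥ 3 use the exact
recursive (IIR) B-spline prefilter with mirror boundaries, so the
interpolant passes through the original samples (identity transforms and
integer-voxel shifts reproduce the input to numerical precision — both are
asserted in the tests). Out-of-field voxels receive a background constant.
The implementation is compiled (Rcpp); a whole-volume 5th-order resample
of a 44×44×48 grid takes on the order of 0.1 s.

**Mode estimation.** Intensity modes are density peaks (bandwidth =
range/128, evaluation range padded past the data so boundary modes remain
detectable) ranked by *local mass* rather than raw height, then refined as
the centroid of each peak's top half. Mass ranking matters because
high-order interpolation leaves a narrow overshoot ridge beside sharp
edges which can out-peak a thin tissue plateau; a plateau always carries
more mass. Peaks must also be separated by deep valleys (the minimum
between adjacent modes below half the smaller peak), which rejects
unimodal noise volumes instead of segmenting them. Everything scales with
the intensity range, making the mask invariant under affine intensity
rescaling.

**Centerline.** Per-slice centroids are unweighted means of mask pixel
centers. $x(z)$ and $y(z)$ are cubic smoothing splines whose equivalent
degrees of freedom are selected by AICc over df 3–15 (both axes pooled):
straight cords get the minimal df, so the derivative does not chase
centroid quantization noise, while curved cords get enough df to track the
curve. Angles come from the analytic spline derivative. The first and last
four populated slices are excluded from angle statistics — spline
derivative edge effects extend roughly that far, which is why the margin
is wider than a minimal two-slice trim.

**Statistics.** Sample SDs use the $n-1$ denominator throughout. Sample
sizes are rounded up (ceiling, with a $10^{-9}$ guard against
floating-point overshoot) and floored at one per arm; the unpaired result
is reported per arm with a 1:1 allocation total. The z-score convention is
$z_{\alpha/2} = \Phi^{-1}(\alpha/2)$, $z_\beta = \Phi^{-1}(1-\mathrm{power})$
(both negative in the usual cases; only their squared sum enters the
formulas). The worked 90 %-power example (σ = 7.59 mm², Δ = 6.97 mm² →
25 per arm, 50 total) is cross-checked in the tests by an independent
brute-force simulation of the corresponding t-test: 80 % power would give
19 per arm, so the 90 % level is the one consistent with 50 subjects. The
Monte Carlo sample-size procedure draws, per iteration, one transform per
subject per condition (two independent draws per subject for the paired
design), recomputes the σ terms and n, and summarizes mean ± SD over
iterations; Δ is held at the grand unscaled mean across all records.

**Error statistic.** `csa_error()` reports both the absolute form (mean
over subjects of $\mu_t\{CSA_r\} - \mu_t\{CSA_1\}\,r^2$, exactly zero at
$r = 1$ and whenever measurements obey the $r^2$ law) and a percent form
normalized by the expected scaled CSA, which is the form convenient for
cross-resolution comparison.

**Missing data.** Empty mask slices are flagged missing and excluded from
level averaging with a warning rather than entering as zero area. Frozen
transform CSVs are serialized with `%.17g` and re-parsed with
correctly-rounded `strtod`, so replay is bit-exact; rows violating the
declared sampling bounds still load (with a warning and a flag) because a
frozen run must replay even after the bounds change.

## What the phantom does and does not emulate

The generator reproduces the features the evaluation actually exercises:
known per-slice CSA, a realistic CSA spread across subjects, two contrast
polarities and grid resolutions, curvature within the small-angle regime
(max 20°, keeping the elliptical-slice model valid), level labels, and
additive Gaussian noise. It does **not** emulate Rician noise, bias
fields, motion or ghosting artifacts, non-circular cord cross-sections,
or pathology-related signal change — so passing tests demonstrate the
*pipeline's* fidelity (geometry, interpolation, segmentation consistency,
statistics), not robustness to real-MRI artifacts.

One phantom-specific artifact deserves mention: the volume is rasterized
binarily (a voxel is cord iff its center falls inside the ellipse), so the
object's boundary is jagged at the voxel scale. Measuring the *same*
jagged object after a rigid move is exact, but after sub-voxel scaling the
boundary re-rasterizes against the lattice, adding draw-to-draw
fluctuation at scaled conditions that partial-volume imaging of smooth
anatomy would not show. Slice and transform averaging (as the pipeline's
statistics always do) suppresses it; per-draw scaled measurements on
straight cords are the worst case.

## Problem sizes

The shipped tests run the full chain at 44×44×48–52×44×48 voxels, cohorts
of up to 8 imaged subjects (200 at the statistics level), 30 rigid draws
for the rotation-invariance property, and 500-iteration Monte Carlo
sample-size runs; the whole suite takes well under a minute on one CPU.
These sizes were chosen so every property is measurable with margin while
keeping the package's checks quick to run; all of them scale up through
`run_config()` without code changes.

## Known limitations

* The reference segmenter assumes three well-separated intensity modes
  with the background darkest; it is a stand-in for learned segmenters,
  valid on phantoms, not on real MRI.
* Angle correction assumes a locally cylindrical cord; at angles beyond
  ~20° or at kinks the elliptical-slice model (and hence the correction)
  degrades, which is why the generator enforces the 20° limit.
* The paired-design Monte Carlo at large atrophies saturates at n = 1–2;
  its interesting regime is the sub-2 % atrophy grid.
* Intensity-based segmentation of the binary phantom inherits the
  re-rasterization noise described above at scaled conditions.
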