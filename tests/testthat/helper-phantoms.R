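# shared fixtures and independent oracles, built in code at test time

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# constant lateral offset centerline; used to dither the cord against the
# voxel lattice (golden-ratio / sqrt(2) phases sample the unit cell evenly)
offset_centerline <- function(ox, oy, slope_x = 0) {
  list(cx = function(z) ox + slope_x * z,
       cy = function(z) rep(oy, length(z)))
}

lattice_phases <- function(k, h) {
  data.frame(ox = (k * 0.6180339887) %% 1 * h,
             oy = (k * 0.4142135624) %% 1 * h)
}

# mean segmented slice area of a straight (possibly tilted) cord, averaged
# over lattice phases so single-alignment rasterization bias cancels
dithered_mean_area <- function(theta_deg, n_phases = 6, voxel = 0.8,
                               grid = c(52L, 44L, 48L), slices = 9:40) {
  slope <- tanpi(theta_deg / 180)
  mean(vapply(seq_len(n_phases), function(k) {
    ph <- lattice_phases(k, voxel)
    sp <- phantom_spec(voxel_size_mm = voxel, grid_shape = grid,
                       centerline = offset_centerline(ph$ox, ph$oy, slope))
    m <- segment_reference(generate_phantom(sp)$volume, "t2")
    mean(slice_areas(m)$area_mm2[slices])
  }, 1.0))
}

# curved test phantom shared by the resampling properties
curved_phantom <- function(voxel = 0.8, grid = c(44L, 44L, 48L)) {
  generate_phantom(phantom_spec(
    voxel_size_mm = voxel, grid_shape = grid,
    centerline = centerline_sinusoidal(1.5, 60)))
}

# full measurement of one resampled cell: segment, fit centerline, average
# angle-corrected slice areas over interior slices
measure_csa_slices <- function(volume, transform, contrast = "t2",
                               background = 20, slices = 9:40) {
  m <- segment_reference(resample(volume, transform, order = 5,
                                  background = background), contrast)
  cl <- fit_centerline(m)
  sa <- merge(slice_areas(m), cl[, c("z_index", "theta_deg")])
  mean(corrected_area(sa$area_mm2[slices], sa$theta_deg[slices]))
}

# independent empirical-power oracle: simulate the t-test the sample-size
# formula approximates and return the rejection rate
empirical_power_unpaired <- function(n, sigma, delta, alpha = 0.05,
                                     reps = 1e4, seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n * reps, 0, sigma), n)
  x2 <- matrix(rnorm(n * reps, delta, sigma), n)
  tstat <- (colMeans(x2) - colMeans(x1)) /
    sqrt((apply(x1, 2, var) + apply(x2, 2, var)) / n)
  mean(abs(tstat) > qt(1 - alpha / 2, 2 * n - 2))
}

empirical_power_paired <- function(n, sigma_diff, delta, alpha = 0.05,
                                   reps = 1e4, seed = 1) {
  set.seed(seed)
  d <- matrix(rnorm(n * reps, delta, sigma_diff), n)
  tstat <- colMeans(d) / (apply(d, 2, sd) / sqrt(n))
  mean(abs(tstat) > qt(1 - alpha / 2, n - 1))
}

# small pipeline configuration used by the pipeline tests
tiny_config <- function(...) {
  run_config(n_subjects = 3, contrasts = "t2", grid_shape = c(32L, 32L, 32L),
             scalings = c(1, 0.95), n_transforms = 2, mc_iterations = 25,
             powers = 0.8, seed = 7L, ...)
}
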