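test_that("a straight 80 mm^2 cord has exactly that true CSA on every slice", {
  sp <- phantom_spec(cord_radius_mm = sqrt(80 / pi), voxel_size_mm = 1,
                     grid_shape = c(32, 32, 20))
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$per_slice$true_csa_mm2, rep(80, 20))
  expect_true(all(slice_areas(ph$truth$true_mask)$n_pixels > 0))
})

test_that("phantom generation is bit-identical for the same seed", {
  sp <- phantom_spec(noise_sd = 5, seed = 123, grid_shape = c(24, 24, 16))
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$true_mask$data, b$truth$true_mask$data)
  sp2 <- phantom_spec(noise_sd = 5, seed = 124, grid_shape = c(24, 24, 16))
  expect_false(identical(generate_phantom(sp2)$volume$data, a$volume$data))
})

test_that("rasterized mask area matches the analytic disc area", {
  # brute-force oracle: count lattice points inside the circle directly
  h <- 0.5
  xs <- seq(-12, 12, by = h)
  oracle <- sum(outer(xs^2, xs^2, `+`) <= 25) * h^2
  expect_lt(abs(oracle - pi * 25) / (pi * 25), 0.02)
  sp <- phantom_spec(cord_radius_mm = 5, voxel_size_mm = h,
                     grid_shape = c(49, 49, 12))
  mid <- slice_area(generate_phantom(sp)$truth$true_mask, 6)
  expect_equal(as.numeric(mid), oracle)
  expect_lt(abs(mid - pi * 25) / (pi * 25), 0.02)
})

test_that("phase-averaged rasterization error shrinks monotonically with voxel size", {
  R <- sqrt(80 / pi)
  err <- vapply(c(1.0, 0.8, 0.5, 0.25), function(h) {
    es <- vapply(1:16, function(k) {
      ph <- lattice_phases(k, h)
      n <- ceiling(26 / h)
      sp <- phantom_spec(cord_radius_mm = R,
                         centerline = offset_centerline(ph$ox, ph$oy),
                         voxel_size_mm = h, grid_shape = c(n, n, 6))
      mean(slice_areas(generate_phantom(sp)$truth$true_mask)$area_mm2) - 80
    }, 1.0)
    mean(abs(es))
  }, 1.0)
  expect_true(all(diff(err) < 0))
})

test_that("level bands partition the labeled extent and drive C3-C5 selection", {
  sp <- phantom_spec(grid_shape = c(24, 24, 35), voxel_size_mm = 1)
  ph <- generate_phantom(sp)
  lab <- ph$truth$level_labels
  expect_true(all(!is.na(lab)))
  expect_identical(sort(unique(lab)), paste0("C", 1:7))
  rec <- compute_csa(ph$truth$true_mask, lab, levels = c("C3", "C5"),
                     angle_correction = FALSE)
  expect_identical(rec$n_slices, sum(lab %in% c("C3", "C4", "C5")))
})

test_that("invalid geometry is rejected", {
  expect_error(phantom_spec(cord_radius_mm = -1), "radius")
  expect_error(phantom_spec(cord_radius_mm = 12, grid_shape = c(24, 24, 16)),
               "exits the grid")
  expect_no_error(phantom_spec(centerline = centerline_tilted(19.99),
                               grid_shape = c(200, 48, 48)))
  expect_error(phantom_spec(centerline = list(
    cx = function(z) 0.6 * z, cy = function(z) rep(0, length(z)))),
    "20 deg")
  expect_error(phantom_spec(contrast = "t1",
                            intensities = c(cord = 50, csf = 60,
                                            background = 20)),
               "t1-like")
})

test_that("cohort radii hit the target CSA dispersion", {
  specs <- cohort_specs(200, mean_csa_mm2 = 70, csa_cov_percent = 10,
                        seed = 42, grid_shape = c(48, 48, 16))
  subj <- attr(specs, "subjects")
  csa <- subj$true_csa_mm2
  cov <- 100 * sd(csa) / mean(csa)
  expect_gt(cov, 8.5)
  expect_lt(cov, 11.5)
  # SD approx COV x mean: sampling SE of the SD at n = 200 is ~0.35 mm^2
  expect_lt(abs(sd(csa) - 7), 1.1)
  # each subject reproducible from (seed, index)
  again <- cohort_specs(200, mean_csa_mm2 = 70, csa_cov_percent = 10,
                        seed = 42, grid_shape = c(48, 48, 16))
  expect_equal(attr(again, "subjects")$cord_radius_mm, subj$cord_radius_mm)
})

test_that("single-subject cohorts and bad dispersions are handled", {
  one <- generate_cohort(1, seed = 1, grid_shape = c(24, 24, 12))
  expect_length(one, 1)
  expect_s3_class(one[[1]]$volume, "cord_volume")
  expect_error(cohort_specs(5, csa_cov_percent = 40), "non-positive radii")
})

test_that("truth tables serialize per-slice ground truth", {
  coh <- generate_cohort(2, seed = 3, grid_shape = c(24, 24, 14))
  tt <- truth_table(coh)
  expect_named(tt, c("subject", "z", "level", "true_csa_mm2"))
  expect_equal(nrow(tt), 28)
  expect_true(all(tt$true_csa_mm2 > 0))
})

test_that("volumes survive a NIfTI round trip", {
  sp <- phantom_spec(grid_shape = c(16, 16, 10), noise_sd = 2, seed = 5)
  v <- generate_phantom(sp)$volume
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_equal(back$voxel_size_mm, v$voxel_size_mm, tolerance = 1e-6)
  expect_equal(back$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
})
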