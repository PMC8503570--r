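test_that("slice areas are pixel count times pixel area, with missing flags", {
  m <- array(0L, dim = c(20, 20, 5))
  m[5:14, 5:14, 2] <- 1L  # 100 pixels
  mask <- cord_volume(m, 0.8)
  sa <- slice_areas(mask)
  expect_equal(sa$area_mm2[2], 64.0)
  expect_true(sa$missing[1])
  expect_true(is.na(sa$area_mm2[1]))
  expect_equal(as.numeric(slice_area(mask, 2)), 64.0)
  flagged <- slice_area(mask, 1)
  expect_true(is.na(flagged))
  expect_true(attr(flagged, "missing"))
  expect_error(slice_area(mask, 9), "does not exist")
})

test_that("centerline angles are recovered for straight, tilted and curved cords", {
  straight <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 40),
                                            voxel_size_mm = 0.8))
  cl <- fit_centerline(straight$truth$true_mask)
  expect_lt(max(cl$theta_deg[cl$interior]), 0.1)

  tilted <- generate_phantom(phantom_spec(
    grid_shape = c(64, 32, 40), voxel_size_mm = 0.8,
    centerline = centerline_tilted(10)))
  cl <- fit_centerline(tilted$truth$true_mask)
  expect_lt(max(abs(cl$theta_deg[cl$interior] - 10)), 0.5)

  wave <- generate_phantom(phantom_spec(
    grid_shape = c(44, 44, 60), voxel_size_mm = 0.8,
    centerline = centerline_sinusoidal(2, 60)))
  cl <- fit_centerline(wave$truth$true_mask)
  zc <- 60 * 0.8 / 2
  true_theta <- atan(2 * 2 * pi / 60 *
                       abs(cos(2 * pi * (cl$z_mm - zc) / 60))) * 180 / pi
  expect_lt(max(abs(cl$theta_deg - true_theta)[cl$interior]), 1)
})

test_that("centerline fitting needs at least 4 populated slices", {
  m <- array(0L, dim = c(16, 16, 8))
  m[6:10, 6:10, 2:4] <- 1L
  expect_error(fit_centerline(cord_volume(m, 1)), "insufficient")
})

test_that("cosine correction undoes the tilt bias analytically", {
  expect_equal(corrected_area(80, 0), 80)
  expect_equal(corrected_area(80 / cospi(10 / 180), 10), 80)
  expect_equal(corrected_area(81.234, 10), 80, tolerance = 1e-4)
  expect_equal(corrected_area(80, 60), 40)
  expect_error(corrected_area(80, 90), "90")
  expect_error(corrected_area(80, -5), "90")
})

test_that("C3-C5 averaging selects the anatomical slice coverage", {
  # a 50 mm C3-C5 span holds 50 slices at 1.0 mm and 62 at 0.8 mm
  lb <- tibble::tibble(level = c("C3", "C4", "C5"),
                       z_min_mm = c(0, 18, 35), z_max_mm = c(18, 35, 50))
  for (case in list(list(h = 1.0, n = 50), list(h = 0.8, n = 62))) {
    nz <- ceiling(52 / case$h)
    sp <- phantom_spec(voxel_size_mm = case$h, grid_shape = c(26, 26, nz),
                       level_boundaries = lb)
    ph <- generate_phantom(sp)
    rec <- compute_csa(ph$truth$true_mask, ph$truth$level_labels,
                       angle_correction = FALSE)
    expect_equal(rec$n_slices, case$n)
    # uniform straight tube: mean equals every slice area
    expect_equal(rec$mean_csa_mm2,
                 as.numeric(slice_area(ph$truth$true_mask, 5)))
  }
})

test_that("missing slices are excluded from the mean with a warning", {
  sp <- phantom_spec(voxel_size_mm = 1, grid_shape = c(26, 26, 35))
  ph <- generate_phantom(sp)
  mask <- ph$truth$true_mask
  labs <- ph$truth$level_labels
  idx <- which(labs == "C4")[2]
  mask$data[, , idx] <- 0L
  expect_warning(rec <- compute_csa(mask, labs, angle_correction = FALSE),
                 "excluded")
  full <- sum(labs %in% c("C3", "C4", "C5"))
  expect_identical(rec$n_slices, full - 1L)
  expect_error(compute_csa(mask, labs, levels = c("X1", "X2")), "no slice")
})

test_that("intra-subject CSA is rotation invariant with angle correction", {
  ph <- curved_phantom()
  v <- ph$volume
  center <- dim(v) * 0.8 / 2
  rig <- sample_rigid(30, seed = 11)
  csas <- vapply(1:30, function(i) {
    tf <- compose_transform(1, rig[i, ], 0.8, center)
    m <- segment_reference(resample(v, tf, order = 5, background = 20), "t2")
    labels <- cordsim:::transform_level_labels(ph, tf)
    compute_csa(m, labels)$mean_csa_mm2
  }, 1.0)
  expect_lt(100 * sd(csas) / mean(csas), 2)
})

test_that("uncorrected tilt bias follows 1/cos(theta)", {
  a0 <- dithered_mean_area(0)
  for (th in c(5, 10, 15)) {
    ratio <- dithered_mean_area(th) / a0
    expect_lt(abs(ratio * cospi(th / 180) - 1), 0.01)
  }
})
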