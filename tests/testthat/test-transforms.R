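test_that("atrophy percent and its inverse follow the r^2 law", {
  expect_equal(atrophy_percent(1), 0)
  expect_equal(atrophy_percent(0.93), 13.51, tolerance = 0.005)
  expect_equal(atrophy_percent(0.998), 0.40, tolerance = 0.005)
  # Table-style header sequences regenerate from the scaling grids
  expect_equal(round(atrophy_percent(seq(0.93, 0.99, by = 0.01)), 2),
               c(13.51, 11.64, 9.75, 7.84, 5.91, 3.96, 1.99))
  expect_equal(round(atrophy_percent(c(0.992, 0.994, 0.996, 0.998)), 2),
               c(1.59, 1.20, 0.80, 0.40))
  r <- seq(0.001, 1, length.out = 200)
  expect_equal(scaling_for_atrophy(atrophy_percent(r)), r, tolerance = 1e-12)
  expect_error(atrophy_percent(1.01), "\\(0, 1\\]")
  expect_error(atrophy_percent(0), "\\(0, 1\\]")
  expect_error(scaling_for_atrophy(100), "\\[0, 100\\)")
})

test_that("x-y-only scaling of a disc follows the ellipse geometry", {
  expect_equal(xy_scaled_area(80, 0.9, 0), 64.8)
  expect_equal(xy_scaled_area(80, 0.9, 10), 65.03, tolerance = 0.005)
  expect_equal(xy_scaled_area(123.4, 1, 37), 123.4)
  expect_error(xy_scaled_area(-1, 0.9, 0), "positive")
  expect_error(xy_scaled_area(80, 0.9, 95), "90")
})

test_that("scaling transforms act about their center with determinant r^3", {
  expect_equal(unclass(scaling_transform(1)), diag(4), ignore_attr = TRUE)
  s <- scaling_transform(0.95, center = c(10, 12, 14))
  expect_equal(det(s[1:3, 1:3]), 0.857375)
  p <- c(13, 7, 20, 1)
  expect_equal((s %*% p)[1:3],
               c(10, 12, 14) + 0.95 * (p[1:3] - c(10, 12, 14)))
  expect_error(scaling_transform(0), "\\(0, 1\\]")
})

test_that("composition keeps the scaled volume factor and converts voxels to mm", {
  rig <- sample_rigid(1, seed = 2)
  tf <- compose_transform(0.9, rig[1, ], voxel_size_mm = 0.8,
                          center = c(16, 16, 16))
  expect_equal(det(tf[1:3, 1:3]), 0.729)
  expect_equal(unclass(compose_transform(1, NULL, 0.8)), diag(4),
               ignore_attr = TRUE)
  shift <- rigid_transform(c(0, 0, 0), c(5, 0, 0), voxel_size_mm = 0.8)
  expect_equal(shift[1:3, 4], c(4, 0, 0))
})

test_that("rigid draws stay in bounds with uniform moments and replay from seed", {
  zero <- sample_rigid(3, rot_bound_deg = 0, trans_bound_vox = 0, seed = 1)
  expect_true(all(zero[, 2:7] == 0))
  big <- sample_rigid(1e4, seed = 99)
  comp <- as.matrix(big[, 2:7])
  expect_true(all(abs(comp[, 1:3]) <= 2.5))
  expect_true(all(abs(comp[, 4:6]) <= 5))
  se_rot <- 2.5 / sqrt(3) / sqrt(1e4)
  se_tr <- 5 / sqrt(3) / sqrt(1e4)
  expect_true(all(abs(colMeans(comp[, 1:3])) < 3 * se_rot))
  expect_true(all(abs(colMeans(comp[, 4:6])) < 3 * se_tr))
  expect_identical(sample_rigid(30, seed = 5), sample_rigid(30, seed = 5))
  expect_error(sample_rigid(10, rot_bound_deg = -1), "non-negative")
})

test_that("resampling is exact for identity and integer-voxel shifts", {
  ph <- curved_phantom(grid = c(32L, 32L, 32L))
  v <- ph$volume
  out <- resample(v, scaling_transform(1), order = 5)
  expect_lt(max(abs(out$data - v$data)), 1e-6 * diff(range(v$data)))
  tr <- rigid_transform(c(0, 0, 0), c(3, 0, 0), 0.8)
  sh <- resample(v, tr, order = 5, background = 20)
  expect_lt(max(abs(sh$data[4:32, , ] - v$data[1:29, , ])),
            1e-6 * diff(range(v$data)))
  expect_error(resample(v, matrix(0, 4, 4)), "singular")
})

test_that("measured CSA follows the r^2 area-scaling law after one resampling", {
  ph <- curved_phantom()
  v <- ph$volume
  center <- dim(v) * 0.8 / 2
  rig <- sample_rigid(6, seed = 7)
  measure <- function(r) mean(vapply(1:6, function(i)
    measure_csa_slices(v, compose_transform(r, rig[i, ], 0.8, center)), 1.0))
  a1 <- measure(1)
  for (r in seq(0.93, 0.99, by = 0.01)) {
    expect_lt(abs(measure(r) / a1 - r^2), 0.01)
  }
})

test_that("composed transforms map analytic centerline coordinates exactly", {
  rig <- sample_rigid(1, seed = 3)
  center <- c(16, 16, 16)
  s <- scaling_transform(0.94, center)
  tf <- compose_transform(0.94, rig[1, ], 0.8, center)
  rg <- rigid_transform(as.numeric(rig[1, c("rot_x_deg", "rot_y_deg",
                                            "rot_z_deg")]),
                        as.numeric(rig[1, c("trans_x_vox", "trans_y_vox",
                                            "trans_z_vox")]), 0.8, center)
  pts <- rbind(runif(5, 0, 32), runif(5, 0, 32), runif(5, 0, 32), 1)
  expect_equal(unclass(tf) %*% pts, unclass(rg) %*% (unclass(s) %*% pts),
               tolerance = 1e-12)
})

test_that("frozen transforms round-trip losslessly and replay out-of-bound rows", {
  draws <- sample_rigid(30, seed = 13)
  grid <- dplyr::mutate(draws, subject = "sub-001", scaling_r = 0.95,
                        .before = 1)
  path <- tempfile(fileext = ".csv")
  freeze_transforms(grid, path)
  back <- load_transforms(path)
  for (col in c("rot_x_deg", "rot_y_deg", "rot_z_deg",
                "trans_x_vox", "trans_y_vox", "trans_z_vox"))
    expect_identical(back[[col]], grid[[col]])
  expect_false(any(back$bound_violation))

  empty <- grid[0, ]
  freeze_transforms(empty, path)
  expect_equal(nrow(load_transforms(path)), 0)

  bad <- grid[1:2, ]
  bad$rot_x_deg[2] <- 9
  freeze_transforms(bad, path)
  expect_warning(loaded <- load_transforms(path), "violate")
  expect_identical(loaded$bound_violation, c(FALSE, TRUE))

  writeLines(c(paste(cordsim:::transform_csv_columns(), collapse = ","),
               "sub-001,1,0,0,0,0,0,0,0,1",
               "sub-001,1,not_a_number,0,0,0,0,0,0,1"), path)
  expect_error(load_transforms(path), "line 3")
})
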