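test_that("z-score conventions match the sample-size formulas", {
  expect_equal(z_score(0.2), -0.84, tolerance = 0.005)
  expect_equal(z_score(0.025), -1.96, tolerance = 0.005)
  expect_equal(z_score(0.5), 0)
  expect_error(z_score(0), "\\(0, 1\\)")
  expect_error(z_score(1), "\\(0, 1\\)")
})

test_that("the expected group difference scales with 1 - r^2", {
  expect_equal(delta_group(123, 1), 0)
  expect_equal(delta_group(69.7, scaling_for_atrophy(10)), 6.97)
  expect_equal(delta_group(70, 0.99), 1.393)
  expect_error(delta_group(-1, 0.9), "positive")
})

test_that("intra- and inter-subject statistics match hand arithmetic", {
  recs <- tibble::tibble(
    subject_id = c("a", "a", "b", "b"),
    scaling_r = 1, transform_index = c(0L, 1L, 0L, 1L),
    mean_csa_mm2 = c(64, 66, 80, 80))
  intra <- intra_subject_stats(recs)
  expect_equal(intra$sigma_t[intra$subject_id == "a"], sqrt(2))
  expect_equal(intra$cov_t_percent[intra$subject_id == "a"],
               100 * sqrt(2) / 65)
  expect_equal(intra$sigma_t[intra$subject_id == "b"], 0)

  # subject means 65 and 80
  inter <- inter_subject_stats(recs)
  expect_equal(inter$sigma_s, sd(c(65, 80)))
  expect_equal(inter$cov_s_percent, 100 * sd(c(65, 80)) / 72.5)

  # two subjects with transform means 60 and 80
  recs2 <- tibble::tibble(subject_id = c("a", "b"), scaling_r = 1,
                          transform_index = 0L, mean_csa_mm2 = c(60, 80))
  inter2 <- inter_subject_stats(recs2)
  expect_equal(inter2$sigma_s, sqrt(200))
  expect_equal(inter2$cov_s_percent, 100 * sqrt(200) / 70)

  single <- intra_subject_stats(recs2)
  expect_true(all(is.na(single$sigma_t)))
})

test_that("the CSA error statistic is zero under the exact r^2 law", {
  base <- tibble::tibble(subject_id = rep(c("a", "b"), each = 2),
                         scaling_r = 1, transform_index = rep(c(0L, 1L), 2),
                         mean_csa_mm2 = c(70, 72, 64, 66))
  scaled <- dplyr::mutate(base, scaling_r = 0.95,
                          mean_csa_mm2 = mean_csa_mm2 * 0.95^2)
  err <- csa_error(dplyr::bind_rows(base, scaled))
  expect_equal(err$mean_error_mm2, c(0, 0), tolerance = 1e-12)
  expect_equal(err$mean_error_percent, c(0, 0), tolerance = 1e-12)

  one <- tibble::tibble(subject_id = "a", scaling_r = c(1, 0.9),
                        transform_index = 0L, mean_csa_mm2 = c(80, 65.8))
  err1 <- csa_error(one)
  expect_equal(err1$mean_error_mm2[err1$scaling_r == 0.9], 1.0)

  noone <- dplyr::filter(dplyr::bind_rows(base, scaled),
                         !(subject_id == "b" & scaling_r == 1))
  expect_error(csa_error(noone), "sub.*b")
})

test_that("unpaired sample sizes reproduce the worked example and scale correctly", {
  res <- sample_size_unpaired(7.59, 7.59, 6.97, alpha = 0.05, power = 0.90)
  expect_identical(res$n_per_arm, 25L)
  expect_identical(res$n_total, 50L)
  expect_identical(sample_size_unpaired(1, 1, 1, 0.05, 0.8)$n_per_arm, 16L)
  expect_identical(sample_size_unpaired(1, 1, 1e6, 0.05, 0.8)$n_per_arm, 1L)
  expect_error(sample_size_unpaired(1, 1, 0), "infinite|positive")
})

test_that("paired sample sizes follow the sigma_diff formula", {
  expect_identical(sample_size_paired(1, 1, 0.05, 0.8)$n_per_arm, 8L)
  expect_identical(sample_size_paired(0, 1)$n_per_arm, 1L)
  # doubling delta divides the pre-ceiling n by 4
  zsum2 <- (z_score(0.025) + z_score(0.2))^2
  expect_equal((zsum2 * 9 / 1) / (zsum2 * 9 / 4), 4)
  expect_error(sample_size_paired(1, 0), "infinite|positive")
})

test_that("sample sizes are monotone in delta, sigma and power", {
  n_grid <- vapply(c(2, 4, 6), function(d)
    sample_size_unpaired(7, 7, d)$n_per_arm, 1L)
  expect_true(all(diff(n_grid) < 0))
  s_grid <- vapply(c(4, 6, 8), function(s)
    sample_size_unpaired(s, s, 5)$n_per_arm, 1L)
  expect_true(all(diff(s_grid) > 0))
  expect_gte(sample_size_unpaired(7, 7, 5, power = 0.9)$n_per_arm,
             sample_size_unpaired(7, 7, 5, power = 0.8)$n_per_arm)
  expect_gte(sample_size_paired(3, 1, power = 0.9)$n_per_arm,
             sample_size_paired(3, 1, power = 0.8)$n_per_arm)
})

test_that("tidy and glance summarize sample-size results", {
  res <- sample_size_unpaired(7.59, 7.59, 6.97, power = 0.9)
  td <- generics::tidy(res)
  expect_identical(td$n_total, 50L)
  gl <- generics::glance(res)
  expect_equal(gl$z_alpha_half, qnorm(0.025))
  expect_equal(gl$power, 0.9)
})

test_that("Monte Carlo sample size degenerates correctly", {
  recs <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 4),
    scaling_r = rep(c(1, 1, 0.95, 0.95), 3),
    transform_index = rep(c(0L, 1L), 6),
    mean_csa_mm2 = rep(c(70, 70, 63.175, 63.175), 3) +
      rep(c(0, 5, -5), each = 4))
  # identical transform records per subject: no draw variability
  res <- monte_carlo_sample_size(recs, 0.95, "unpaired", iterations = 20,
                                 seed = 1)
  expect_equal(res$mc_sd, 0)
  one <- monte_carlo_sample_size(recs, 0.95, "unpaired", iterations = 1,
                                 seed = 1)
  expect_equal(one$mc_mean, one$n_per_arm)
  expect_equal(one$mc_sd, 0)
  expect_error(monte_carlo_sample_size(recs[recs$subject_id == "a", ], 0.95),
               ">= 2 subjects")
})

test_that("simulated cohorts recover their generating variability", {
  recs <- simulate_csa_records(200, mean_csa_mm2 = 70, cov_inter_percent = 10,
                               cov_intra_percent = 0.7,
                               scalings = c(1, 0.95), n_transforms = 10,
                               seed = 31)
  st <- cohort_stats(recs)
  expect_equal(st$grand_mean_mm2[st$scaling_r == 1], 70, tolerance = 0.05)
  expect_gt(st$cov_s_percent[st$scaling_r == 1], 8.5)
  expect_lt(st$cov_s_percent[st$scaling_r == 1], 11.5)
  expect_equal(st$mean_cov_t_percent, c(0.7, 0.7), tolerance = 0.1)
  err <- csa_error(recs)
  expect_equal(err$mean_error_mm2[err$scaling_r == 1], 0)
  expect_lt(abs(err$mean_error_mm2[err$scaling_r == 0.95]), 0.1)
})
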