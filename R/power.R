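#' Tail z-score
#'
#' Standard-normal quantile of a tail probability, with the sign convention
#' used in the sample-size formulas: a 5% two-sided significance level gives
#' `z_score(0.025) = -1.96` and 80% power gives `z_score(0.2) = -0.84`; only
#' the square of the sum enters the formulas.
#'
#' @param p Tail probability in (0, 1).
#' @return Standard-normal quantile.
#' @export
z_score <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("tail probability must lie in (0, 1)", call. = FALSE)
  qnorm(p)
}

#' Expected between-group CSA difference for a given atrophy
#'
#' The theoretical mean CSA difference between an atrophic group scaled by
#' `r` and a control group: `Delta = mean_csa * (1 - r^2)`.
#'
#' @param mean_csa Grand mean unscaled CSA (mm^2), positive.
#' @param r Scaling factor in (0, 1].
#' @return Difference in mm^2.
#' @examples
#' delta_group(69.7, scaling_for_atrophy(10))  # 6.97
#' @export
delta_group <- function(mean_csa, r) {
  if (any(mean_csa <= 0)) stop("mean_csa must be positive", call. = FALSE)
  check_scaling(r)
  mean_csa * (1 - r^2)
}

check_records <- function(records,
                          required = c("subject_id", "scaling_r",
                                       "transform_index", "mean_csa_mm2")) {
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("CSA records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Intra-subject (scan-rescan) CSA variability
#'
#' For each subject and scaling, the standard deviation (n-1 denominator)
#' and coefficient of variation of CSA across Monte Carlo transforms — the
#' simulated scan-rescan precision. Cells with fewer than 2 transform
#' records are flagged undefined (`NA`).
#'
#' @param records Tibble of CSA records with columns `subject_id`,
#'   `scaling_r`, `transform_index`, `mean_csa_mm2` (as produced by
#'   [compute_csa()] / [run_pipeline()]).
#' @return Tibble: `subject_id`, `scaling_r`, `n_transforms`, `mu_t`
#'   (mm^2), `sigma_t` (mm^2), `cov_t_percent`.
#' @export
intra_subject_stats <- function(records) {
  check_records(records)
  records |>
    dplyr::group_by(.data$subject_id, .data$scaling_r) |>
    dplyr::summarise(
      n_transforms = dplyr::n(),
      mu_t = mean(.data$mean_csa_mm2),
      sigma_t = if (dplyr::n() >= 2) sd(.data$mean_csa_mm2) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(cov_t_percent = 100 * .data$sigma_t / .data$mu_t)
}

#' Inter-subject CSA variability
#'
#' Per-subject means across transforms first, then the standard deviation
#' and COV across subjects, for each scaling. Requires at least 2 subjects
#' (flagged `NA` otherwise).
#'
#' @inheritParams intra_subject_stats
#' @return Tibble: `scaling_r`, `n_subjects`, `grand_mean_mm2`
#'   (mean over subjects of per-subject transform means), `sigma_s`
#'   (mm^2), `cov_s_percent`.
#' @export
inter_subject_stats <- function(records) {
  check_records(records)
  intra_subject_stats(records) |>
    dplyr::group_by(.data$scaling_r) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      grand_mean_mm2 = mean(.data$mu_t),
      sigma_s = if (dplyr::n() >= 2) sd(.data$mu_t) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(cov_s_percent = 100 * .data$sigma_s / .data$grand_mean_mm2)
}

#' Cohort variability summary
#'
#' Combines intra- and inter-subject statistics per scaling: the grand mean
#' CSA, the subject-averaged intra-subject SD and COV, and the
#' inter-subject SD and COV.
#'
#' @inheritParams intra_subject_stats
#' @return Tibble: `scaling_r`, `atrophy_percent`, `n_subjects`,
#'   `grand_mean_mm2`, `mean_sigma_t`, `mean_cov_t_percent`, `sigma_s`,
#'   `cov_s_percent`.
#' @export
cohort_stats <- function(records) {
  intra <- intra_subject_stats(records) |>
    dplyr::group_by(.data$scaling_r) |>
    dplyr::summarise(mean_sigma_t = mean(.data$sigma_t),
                     mean_cov_t_percent = mean(.data$cov_t_percent),
                     .groups = "drop")
  inter_subject_stats(records) |>
    dplyr::left_join(intra, by = "scaling_r") |>
    dplyr::mutate(atrophy_percent = atrophy_percent(.data$scaling_r)) |>
    dplyr::select("scaling_r", "atrophy_percent", "n_subjects",
                  "grand_mean_mm2", "mean_sigma_t", "mean_cov_t_percent",
                  "sigma_s", "cov_s_percent")
}

#' CSA error relative to the theoretical scaling law
#'
#' For each scaling `r`, the mean over subjects of
#' `mu_t(CSA_r) - mu_t(CSA_1) * r^2`: how far the measured scaled CSA
#' departs from the unscaled measurement reduced by the known area factor.
#' The percent form normalizes each subject's difference by the expected
#' scaled CSA `mu_t(CSA_1) * r^2` before averaging. Exactly zero at
#' `r = 1` and whenever the measurements obey the `r^2` law.
#'
#' @inheritParams intra_subject_stats
#' @param contrast Optional contrast column to stratify by, if present in
#'   `records`.
#' @return Tibble: (`contrast`,) `scaling_r`, `atrophy_percent`,
#'   `mean_error_mm2`, `mean_error_percent`.
#' @export
csa_error <- function(records) {
  check_records(records)
  has_contrast <- "contrast" %in% names(records) &&
    !all(is.na(records$contrast))
  keys <- if (has_contrast) c("contrast", "subject_id") else "subject_id"
  per_subj <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "scaling_r")))) |>
    dplyr::summarise(mu_t = mean(.data$mean_csa_mm2), .groups = "drop")
  base <- per_subj |>
    dplyr::filter(.data$scaling_r == 1) |>
    dplyr::select(dplyr::all_of(keys), mu_t_unscaled = "mu_t")
  joined <- per_subj |>
    dplyr::left_join(base, by = keys)
  if (any(is.na(joined$mu_t_unscaled))) {
    bad <- unique(joined$subject_id[is.na(joined$mu_t_unscaled)])
    stop("missing unscaled (r = 1) records for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  joined |>
    dplyr::mutate(expected = .data$mu_t_unscaled * .data$scaling_r^2) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(if (has_contrast) "contrast", "scaling_r")))) |>
    dplyr::summarise(
      mean_error_mm2 = mean(.data$mu_t - .data$expected),
      mean_error_percent = mean(100 * (.data$mu_t - .data$expected) /
                                  .data$expected),
      .groups = "drop") |>
    dplyr::mutate(atrophy_percent = atrophy_percent(.data$scaling_r))
}

new_sample_size_result <- function(design, alpha, power, sigma1 = NA_real_,
                                   sigma2 = NA_real_, sigma_diff = NA_real_,
                                   delta, n, mc_mean = NA_real_,
                                   mc_sd = NA_real_) {
  structure(list(
    design = design, alpha = alpha, power = power,
    z_alpha_half = z_score(alpha / 2), z_beta = z_score(1 - power),
    sigma1 = sigma1, sigma2 = sigma2, sigma_diff = sigma_diff,
    delta_mm2 = delta,
    n_per_arm = n, n_total = if (design == "unpaired") 2L * n else n,
    mc_mean = mc_mean, mc_sd = mc_sd), class = "sample_size_result")
}

#' Minimum sample size, unpaired (cross-sectional) design
#'
#' Minimum subjects per arm to detect a mean CSA difference `Delta` between
#' two independent groups with a two-sample bilateral t-test:
#' `n = ceil[ (z_{alpha/2} + z_beta)^2 (sigma1^2 + sigma2^2) / Delta^2 ]`,
#' with `sigma1`, `sigma2` the inter-subject SDs of the scaled and unscaled
#' CSA. Reported per arm, with `n_total = 2 n` (1:1 allocation).
#'
#' @param sigma_scaled,sigma_unscaled Inter-subject SDs (mm^2), >= 0.
#' @param delta Expected group difference (mm^2), > 0 (see [delta_group()]).
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @return A `sample_size_result`; see also [tidy()] and [glance()] methods.
#' @examples
#' sample_size_unpaired(7.59, 7.59, 6.97, power = 0.90)  # 25 per arm
#' @export
sample_size_unpaired <- function(sigma_scaled, sigma_unscaled, delta,
                                 alpha = 0.05, power = 0.8) {
  if (sigma_scaled < 0 || sigma_unscaled < 0)
    stop("sigmas must be non-negative", call. = FALSE)
  if (delta <= 0)
    stop("delta must be positive (an atrophy of 0 needs an infinite sample)",
         call. = FALSE)
  zsum2 <- (z_score(alpha / 2) + z_score(1 - power))^2
  n <- max(1L, as.integer(ceiling(
    zsum2 * (sigma_scaled^2 + sigma_unscaled^2) / delta^2 - 1e-9)))
  new_sample_size_result("unpaired", alpha, power, sigma1 = sigma_scaled,
                         sigma2 = sigma_unscaled, delta = delta, n = n)
}

#' Minimum sample size, paired (longitudinal) design
#'
#' Minimum subjects to detect a within-subject CSA change `Delta` with a
#' bilateral paired t-test:
#' `n = ceil[ (z_{alpha/2} + z_beta)^2 sigma_diff^2 / Delta^2 ]`, with
#' `sigma_diff` the SD across subjects of the (unscaled - scaled) CSA
#' difference.
#'
#' @param sigma_diff SD of the paired difference (mm^2), >= 0.
#' @inheritParams sample_size_unpaired
#' @return A `sample_size_result`.
#' @export
sample_size_paired <- function(sigma_diff, delta, alpha = 0.05, power = 0.8) {
  if (sigma_diff < 0) stop("sigma_diff must be non-negative", call. = FALSE)
  if (delta <= 0)
    stop("delta must be positive (an atrophy of 0 needs an infinite sample)",
         call. = FALSE)
  zsum2 <- (z_score(alpha / 2) + z_score(1 - power))^2
  n <- max(1L, as.integer(ceiling(zsum2 * sigma_diff^2 / delta^2 - 1e-9)))
  new_sample_size_result("paired", alpha, power, sigma_diff = sigma_diff,
                         delta = delta, n = n)
}

#' Monte Carlo sample-size variability
#'
#' Emulates "true" study conditions where each subject is scanned once:
#' per iteration, one transform record is drawn per subject for the scaled
#' condition and one for the unscaled condition (two independent draws per
#' subject for the paired design), the sigma terms and `Delta` (from the
#' grand unscaled mean over all records) are computed from those single
#' draws, and the minimum sample size is derived. The mean and SD of the
#' sample size over iterations are reported.
#'
#' @inheritParams intra_subject_stats
#' @param r Scaling factor of the atrophic condition.
#' @param design `"unpaired"` or `"paired"`.
#' @param alpha,power Test parameters.
#' @param iterations Number of Monte Carlo iterations (default 500).
#' @param seed Integer seed.
#' @return A `sample_size_result` with `mc_mean` and `mc_sd` filled in;
#'   `n_per_arm` is the rounded Monte Carlo mean.
#' @export
monte_carlo_sample_size <- function(records, r, design = c("unpaired",
                                                           "paired"),
                                    alpha = 0.05, power = 0.8,
                                    iterations = 500, seed = 1L) {
  design <- match.arg(design)
  check_records(records)
  check_scaling(r)
  scaled <- records[abs(records$scaling_r - r) < 1e-12, ]
  unscaled <- records[records$scaling_r == 1, ]
  subjects <- intersect(unique(scaled$subject_id), unique(unscaled$subject_id))
  if (length(subjects) < 2)
    stop("need >= 2 subjects with records at both r and 1", call. = FALSE)
  if (nrow(scaled) == 0 || nrow(unscaled) == 0)
    stop("no transform records at the requested scaling", call. = FALSE)
  ms <- split(scaled$mean_csa_mm2, scaled$subject_id)[subjects]
  mu <- split(unscaled$mean_csa_mm2, unscaled$subject_id)[subjects]
  grand_unscaled <- mean(vapply(mu, mean, 1.0))
  delta <- delta_group(grand_unscaled, r)
  draw1 <- function(v) if (length(v) == 1L) v else v[sample.int(length(v), 1L)]
  ns <- with_seed_local(seed, vapply(seq_len(iterations), function(it) {
    cs <- vapply(ms, draw1, 1.0)
    cu <- vapply(mu, draw1, 1.0)
    if (design == "unpaired") {
      sample_size_unpaired(sd(cs), sd(cu), delta, alpha, power)$n_per_arm
    } else {
      sample_size_paired(sd(cu - cs), delta, alpha, power)$n_per_arm
    }
  }, 1L))
  res <- new_sample_size_result(
    design, alpha, power, delta = delta,
    n = max(1L, as.integer(round(mean(ns)))),
    mc_mean = mean(ns), mc_sd = if (iterations > 1) sd(ns) else 0)
  res
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("<sample_size_result> %s design, alpha = %g, power = %g%%\n",
              x$design, x$alpha, 100 * x$power))
  if (x$design == "unpaired")
    cat(sprintf("  sigma_scaled = %.4g, sigma_unscaled = %.4g mm^2\n",
                x$sigma1, x$sigma2))
  else
    cat(sprintf("  sigma_diff = %.4g mm^2\n", x$sigma_diff))
  cat(sprintf("  Delta_group = %.4g mm^2\n", x$delta_mm2))
  if (x$design == "unpaired")
    cat(sprintf("  n = %d per arm (%d total)\n", x$n_per_arm, x$n_total))
  else
    cat(sprintf("  n = %d subjects\n", x$n_per_arm))
  if (!is.na(x$mc_mean))
    cat(sprintf("  Monte Carlo: %.1f +/- %.1f over iterations\n",
                x$mc_mean, x$mc_sd))
  invisible(x)
}

#' Tidy a sample-size result
#'
#' @param x A `sample_size_result`.
#' @param ... Unused.
#' @return `tidy()`: one-row tibble with the sigma terms, `delta_mm2`,
#'   `n_per_arm`, `n_total` and Monte Carlo summaries. `glance()`: one-row
#'   tibble with design, alpha, power and the z-scores.
#' @export
tidy.sample_size_result <- function(x, ...) {
  tibble::tibble(design = x$design, sigma1 = x$sigma1, sigma2 = x$sigma2,
                 sigma_diff = x$sigma_diff, delta_mm2 = x$delta_mm2,
                 n_per_arm = x$n_per_arm, n_total = x$n_total,
                 mc_mean = x$mc_mean, mc_sd = x$mc_sd)
}

#' @rdname tidy.sample_size_result
#' @export
glance.sample_size_result <- function(x, ...) {
  tibble::tibble(design = x$design, alpha = x$alpha, power = x$power,
                 z_alpha_half = x$z_alpha_half, z_beta = x$z_beta,
                 n_per_arm = x$n_per_arm, n_total = x$n_total)
}

#' Simulate CSA records at the statistics level
#'
#' Generates a table of CSA measurements directly from the statistical model
#' the imaging pipeline emulates, bypassing rasterization: subject true CSAs
#' are Gaussian with the given between-subject COV; each measurement at
#' scaling `r` is the true CSA times `r^2` plus Gaussian scan-rescan noise
#' with the given within-subject COV (of the scaled CSA). Useful for testing
#' the statistics stage and for sample-size studies at arbitrary cohort
#' sizes.
#'
#' @param n_subjects Number of subjects.
#' @param mean_csa_mm2 Cohort mean true CSA (mm^2).
#' @param cov_inter_percent Between-subject COV of true CSA (%).
#' @param cov_intra_percent Within-subject (scan-rescan) COV (%).
#' @param scalings Numeric vector of scaling factors (should include 1).
#' @param n_transforms Measurements per subject per scaling.
#' @param seed Integer seed.
#' @return Tibble of CSA records (`subject_id`, `scaling_r`,
#'   `transform_index`, `mean_csa_mm2`, `true_csa_mm2`).
#' @export
simulate_csa_records <- function(n_subjects, mean_csa_mm2 = 70,
                                 cov_inter_percent = 10,
                                 cov_intra_percent = 0.7,
                                 scalings = c(1, 0.95), n_transforms = 30,
                                 seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  check_scaling(scalings)
  with_seed_local(seed, {
    true_csa <- rnorm(n_subjects, mean_csa_mm2,
                      mean_csa_mm2 * cov_inter_percent / 100)
    if (any(true_csa <= 0))
      stop("simulated true CSA not positive; reduce cov_inter_percent",
           call. = FALSE)
    grid <- tidyr::expand_grid(
      subject = seq_len(n_subjects), scaling_r = scalings,
      transform_index = seq_len(n_transforms) - 1L)
    scaled_true <- true_csa[grid$subject] * grid$scaling_r^2
    noise_sd <- scaled_true * cov_intra_percent / 100
    tibble::tibble(
      subject_id = sprintf("sub-%03d", grid$subject),
      scaling_r = grid$scaling_r,
      transform_index = grid$transform_index,
      mean_csa_mm2 = scaled_true + rnorm(nrow(grid), 0, noise_sd),
      true_csa_mm2 = true_csa[grid$subject])
  })
}
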