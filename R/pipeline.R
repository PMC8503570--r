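#' Pipeline run configuration
#'
#' Collects every knob of the simulation grid. Defaults follow the study
#' conditions this package emulates: 30 rigid draws per subject and scaling
#' within +/-2.5 degrees and +/-5 voxels, 5th-order interpolation, CSA
#' averaged over C3-C5 included, alpha 0.05 with 80%/90% power, 500 Monte
#' Carlo iterations for sample-size variability, and the unpaired scaling
#' grid r in \{1.0, 0.99, ..., 0.93\} (atrophies 1.99-13.51%). The paired
#' design grid `paired_scalings()` covers r in \{0.998, ..., 0.992\}
#' (atrophies 0.40-1.59%).
#'
#' @param n_subjects Cohort size.
#' @param mean_csa_mm2,csa_cov_percent Cohort CSA distribution (see
#'   [cohort_specs()]).
#' @param contrasts Character vector of contrasts to simulate; `"t1"` uses a
#'   1.0 mm grid, `"t2"` 0.8 mm, unless `voxel_size_mm` overrides.
#' @param voxel_size_mm Optional named vector of voxel sizes per contrast.
#' @param grid_shape Phantom grid (voxels).
#' @param noise_sd Additive noise SD (intensity units).
#' @param scalings Scaling grid, must include 1 for the statistics stage.
#' @param n_transforms Rigid draws per subject and scaling.
#' @param rot_bound_deg,trans_bound_vox Rigid sampling bounds.
#' @param interp_order Interpolation order (0, 1, 3, 5).
#' @param alpha Two-sided type-I error rate.
#' @param powers Vector of target powers.
#' @param mc_iterations Monte Carlo iterations for sample-size variability.
#' @param levels Closed vertebral-level range for CSA averaging.
#' @param seed Master seed; every random draw in the run derives from it.
#' @param output_dir Optional directory for result CSVs (created if needed);
#'   an existing per-record CSV there is reused (resumable runs).
#' @param csa_csv Optional path to a precomputed CSA record CSV; when given,
#'   the simulation stages are skipped and only statistics are computed.
#' @param reuse_transforms_across_scalings Draw one rigid set per subject
#'   and reuse it across scalings (default FALSE: independent draws).
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 5,
                       mean_csa_mm2 = 70, csa_cov_percent = 10,
                       contrasts = "t2", voxel_size_mm = NULL,
                       grid_shape = c(48L, 48L, 48L), noise_sd = 0,
                       scalings = unpaired_scalings(),
                       n_transforms = 30, rot_bound_deg = 2.5,
                       trans_bound_vox = 5, interp_order = 5,
                       alpha = 0.05, powers = c(0.80, 0.90),
                       mc_iterations = 500, levels = c("C3", "C5"),
                       seed = 1L, output_dir = NULL, csa_csv = NULL,
                       reuse_transforms_across_scalings = FALSE) {
  vs <- c(t1 = 1.0, t2 = 0.8)
  if (!is.null(voxel_size_mm)) vs[names(voxel_size_mm)] <- voxel_size_mm
  stopifnot(all(contrasts %in% names(vs)))
  check_scaling(scalings)
  if (n_subjects < 1 || n_transforms < 1 || mc_iterations < 1)
    stop("all counts must be >= 1", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), mean_csa_mm2 = mean_csa_mm2,
    csa_cov_percent = csa_cov_percent, contrasts = contrasts,
    voxel_size_mm = vs, grid_shape = as.integer(grid_shape),
    noise_sd = noise_sd, scalings = scalings,
    n_transforms = as.integer(n_transforms),
    rot_bound_deg = rot_bound_deg, trans_bound_vox = trans_bound_vox,
    interp_order = as.integer(interp_order), alpha = alpha, powers = powers,
    mc_iterations = as.integer(mc_iterations), levels = levels,
    seed = as.integer(seed), output_dir = output_dir, csa_csv = csa_csv,
    reuse_transforms_across_scalings = reuse_transforms_across_scalings),
    class = "run_config")
}

#' Default scaling grids
#'
#' The unpaired (cross-sectional) grid spans atrophies 1.99-13.51%
#' (r = 0.99...0.93); the paired (longitudinal) grid spans the subtler
#' 0.40-1.59% range (r = 0.998...0.992). Both include r = 1 (no atrophy).
#'
#' @return Numeric vector of scaling factors.
#' @export
unpaired_scalings <- function() c(1, 0.99, 0.98, 0.97, 0.96, 0.95, 0.94, 0.93)

#' @rdname unpaired_scalings
#' @export
paired_scalings <- function() c(1, 0.998, 0.996, 0.994, 0.992)

#' Read a run configuration from YAML
#'
#' Scalar fields in the YAML map directly onto [run_config()] arguments;
#' anything in `overrides` (e.g. parsed command-line flags) wins over the
#' file.
#'
#' @param path YAML file path.
#' @param overrides Named list of overriding arguments.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

# remap per-slice level labels through the anatomy transform: the label of an
# output slice is the label of the input slice whose transformed centerline
# point lands on it
transform_level_labels <- function(phantom, transform) {
  cl <- phantom$truth$centerline
  p <- rbind(cl$cx_mm, cl$cy_mm, cl$z_mm, 1)
  qz <- (unclass(transform) %*% p)[3, ]
  z_out <- phantom$truth$per_slice$z_mm
  ord <- order(qz)
  idx <- round(stats::approx(qz[ord], seq_along(qz)[ord], xout = z_out,
                             rule = 1)$y)
  labels <- rep(NA_character_, length(z_out))
  ok <- !is.na(idx)
  labels[ok] <- phantom$truth$level_labels[idx[ok]]
  labels
}

#' Run the full simulation grid
#'
#' Executes the experiment end to end for every contrast, subject, scaling
#' and rigid draw: phantom generation, composition of the atrophy scaling
#' with the rigid transform, a single resampling, reference segmentation,
#' level-label remapping, angle-corrected CSA, and finally the variability
#' statistics, CSA error summary and minimum sample sizes (including Monte
#' Carlo variability). Any cell failing a stage is flagged and skipped with
#' a warning; the run continues. The whole run is reproducible from the
#' master seed, and when `output_dir` holds a previous per-record CSV those
#' records are reused.
#'
#' @param config A [run_config()].
#' @return A `cordsim_bundle` list: `records` (one row per subject x scaling
#'   x transform), `transforms` (frozen draws), `stats` (per contrast and
#'   scaling, [cohort_stats()]), `error` ([csa_error()]), `sample_sizes`,
#'   `truth` (per-subject true CSA), `failures`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (!is.null(config$csa_csv)) {
    records <- readr::read_csv(config$csa_csv, show_col_types = FALSE)
    check_records(records)
    if (!"contrast" %in% names(records)) records$contrast <- "unspecified"
    transforms <- NULL
    truth <- NULL
    failures <- tibble::tibble()
  } else {
    sim <- simulate_grid(config)
    records <- sim$records
    transforms <- sim$transforms
    truth <- sim$truth
    failures <- sim$failures
  }

  stats_tbl <- records |>
    dplyr::group_by(.data$contrast) |>
    dplyr::group_modify(~ cohort_stats(.x)) |>
    dplyr::ungroup()
  error_tbl <- csa_error(records)

  grid <- tidyr::expand_grid(
    contrast = unique(records$contrast),
    design = c("unpaired", "paired"),
    power = config$powers,
    scaling_r = setdiff(sort(unique(records$scaling_r)), 1))
  sample_sizes <- purrr::pmap_dfr(grid, function(contrast, design, power,
                                                 scaling_r) {
    recs <- records[records$contrast == contrast, ]
    res <- monte_carlo_sample_size(
      recs, r = scaling_r, design = design, alpha = config$alpha,
      power = power, iterations = config$mc_iterations,
      seed = derive_seed(config$seed,
                         round(1e4 * scaling_r) + match(design, c("unpaired",
                                                                  "paired"))))
    tibble::tibble(contrast = contrast, design = design, power = power,
                   scaling_r = scaling_r,
                   atrophy_percent = atrophy_percent(scaling_r),
                   delta_mm2 = res$delta_mm2, n = res$n_per_arm,
                   mc_mean = res$mc_mean, mc_sd = res$mc_sd)
  })

  bundle <- structure(list(records = records, transforms = transforms,
                           stats = stats_tbl, error = error_tbl,
                           sample_sizes = sample_sizes, truth = truth,
                           failures = failures, config = config),
                      class = "cordsim_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

simulate_grid <- function(config) {
  records <- list()
  failures <- list()
  transforms <- list()
  truths <- list()
  prior <- NULL
  if (!is.null(config$output_dir)) {
    rec_path <- file.path(config$output_dir, "csa_records.csv")
    if (file.exists(rec_path))
      prior <- readr::read_csv(rec_path, show_col_types = FALSE)
  }
  for (ci in seq_along(config$contrasts)) {
    contrast <- config$contrasts[ci]
    h <- config$voxel_size_mm[[contrast]]
    cohort <- cohort_specs(
      config$n_subjects, config$mean_csa_mm2, config$csa_cov_percent,
      seed = config$seed, contrast = contrast, voxel_size_mm = h,
      grid_shape = config$grid_shape, noise_sd = config$noise_sd)
    subjects <- attr(cohort, "subjects")
    subjects$contrast <- contrast
    truths[[ci]] <- subjects
    for (si in seq_along(cohort)) {
      phantom <- generate_phantom(cohort[[si]])
      center <- grid_center_mm(phantom$volume)
      bg <- phantom$spec$intensities[["background"]]
      sid <- phantom$spec$subject_id
      for (ri in seq_along(config$scalings)) {
        r <- config$scalings[ri]
        tseed <- derive_seed(config$seed,
                             1000L * si + 101L * ci +
                               if (config$reuse_transforms_across_scalings) 0L
                               else 7919L * ri)
        draws <- sample_rigid(config$n_transforms, config$rot_bound_deg,
                              config$trans_bound_vox, seed = tseed)
        transforms[[length(transforms) + 1L]] <-
          dplyr::mutate(draws, subject = sid, scaling_r = r,
                        contrast = contrast, .before = 1)
        for (ti in seq_len(nrow(draws))) {
          if (!is.null(prior)) {
            hit <- prior[prior$subject_id == sid &
                           prior$contrast == contrast &
                           abs(prior$scaling_r - r) < 1e-12 &
                           prior$transform_index == draws$transform_index[ti], ]
            if (nrow(hit) == 1) {
              records[[length(records) + 1L]] <- hit
              next
            }
          }
          rec <- tryCatch({
            tf <- compose_transform(r, draws[ti, ], h, center)
            moved <- resample(phantom$volume, tf,
                              order = config$interp_order, background = bg)
            mask <- segment_reference(moved, contrast)
            labels <- transform_level_labels(phantom, tf)
            compute_csa(mask, labels, config$levels,
                        subject_id = sid, contrast = contrast,
                        scaling_r = r,
                        transform_index = draws$transform_index[ti]) |>
              dplyr::select(-"per_slice")
          }, error = function(e) {
            warning(sprintf("cell failed (subject %s, r = %g, transform %d): %s",
                            sid, r, draws$transform_index[ti],
                            conditionMessage(e)), call. = FALSE)
            failures[[length(failures) + 1L]] <<- tibble::tibble(
              subject_id = sid, contrast = contrast, scaling_r = r,
              transform_index = draws$transform_index[ti],
              error = conditionMessage(e))
            NULL
          })
          if (!is.null(rec)) records[[length(records) + 1L]] <- rec
        }
      }
    }
  }
  list(records = dplyr::bind_rows(records),
       transforms = dplyr::bind_rows(transforms),
       truth = dplyr::bind_rows(truths),
       failures = dplyr::bind_rows(failures))
}

#' Write a result bundle to CSV files
#'
#' Emits `csa_records.csv`, `transforms.csv`, `cohort_stats.csv`,
#' `error_summary.csv`, `sample_sizes.csv`, `truth.csv` and `config.yaml`
#' into `dir`.
#'
#' @param bundle A `cordsim_bundle` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cordsim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$records, file.path(dir, "csa_records.csv"))
  if (!is.null(bundle$transforms))
    readr::write_csv(bundle$transforms, file.path(dir, "transforms.csv"))
  readr::write_csv(bundle$stats, file.path(dir, "cohort_stats.csv"))
  readr::write_csv(bundle$error, file.path(dir, "error_summary.csv"))
  readr::write_csv(bundle$sample_sizes, file.path(dir, "sample_sizes.csv"))
  if (!is.null(bundle$truth))
    readr::write_csv(bundle$truth, file.path(dir, "truth.csv"))
  cfg <- bundle$config
  cfg$voxel_size_mm <- as.list(cfg$voxel_size_mm)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Format result tables in the conventional wide layout
#'
#' Produces wide tables with one column per simulated atrophy, ordered
#' largest to smallest with the no-atrophy column ("0") last: the mean CSA
#' error (%), the inter-subject COV (%), and one minimum-sample-size table
#' per design and power with `mean +/- sd` cells when the Monte Carlo
#' variability is available.
#'
#' @param bundle A `cordsim_bundle` from [run_pipeline()].
#' @return Named list of tibbles: `error`, `cov`, and
#'   `sample_size_<design>_<power>`.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "cordsim_bundle"))
  if (is.null(bundle$records) || nrow(bundle$records) == 0)
    stop("empty bundle", call. = FALSE)
  fmt_a <- function(a) ifelse(a == 0, "0", sprintf("%.2f", a))
  widen <- function(df, value_col) {
    df$atrophy_label <- fmt_a(round(df$atrophy_percent, 2))
    df <- df[order(-df$atrophy_percent), ]
    tidyr::pivot_wider(
      df[, c("contrast", "atrophy_label", value_col)],
      names_from = "atrophy_label", values_from = dplyr::all_of(value_col))
  }
  out <- list(
    error = widen(bundle$error, "mean_error_percent"),
    cov = widen(dplyr::rename(bundle$stats,
                              cov = "cov_s_percent"), "cov"))
  ss <- bundle$sample_sizes
  ss <- ss[order(-ss$atrophy_percent), ]
  ss$cell <- ifelse(!is.na(ss$mc_sd) & ss$mc_sd > 0,
                    sprintf("%d +/- %.1f", ss$n, ss$mc_sd),
                    as.character(ss$n))
  for (design in unique(ss$design)) {
    for (pw in unique(ss$power)) {
      sub <- ss[ss$design == design & ss$power == pw, ]
      if (nrow(sub) == 0) next
      sub$atrophy_label <- fmt_a(round(sub$atrophy_percent, 2))
      out[[sprintf("sample_size_%s_%d", design, round(100 * pw))]] <-
        tidyr::pivot_wider(sub[, c("contrast", "atrophy_label", "cell")],
                           names_from = "atrophy_label",
                           values_from = "cell")
    }
  }
  out
}
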