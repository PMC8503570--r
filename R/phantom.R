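#' Centerline shape helpers
#'
#' A phantom centerline is a pair of smooth functions `cx(z)`, `cy(z)` giving
#' the lateral (x, y) displacement of the cord center from the grid axis, in
#' mm, as a function of the axial coordinate `z` measured from the axial
#' mid-plane of the grid (so `z = 0` at mid-height).
#'
#' * `centerline_straight()`: a vertical cord on the grid axis.
#' * `centerline_tilted()`: a straight cord tilted by `theta_deg` from the
#'   slice normal, in the x-z (`plane = "xz"`) or y-z plane.
#' * `centerline_sinusoidal()`: a sinusoidal sweep of given amplitude and
#'   period along x, emulating cervical lordotic curvature.
#'
#' @param theta_deg Tilt angle in degrees (0 to <90).
#' @param plane `"xz"` or `"yz"`.
#' @param amplitude_mm,period_mm,phase Sinusoid parameters (mm, mm, radians).
#' @return A list with functions `cx(z)` and `cy(z)`.
#' @export
centerline_straight <- function() {
  list(cx = function(z) rep(0, length(z)), cy = function(z) rep(0, length(z)))
}

#' @rdname centerline_straight
#' @export
centerline_tilted <- function(theta_deg, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  slope <- tanpi(theta_deg / 180)
  f <- function(z) slope * z
  zero <- function(z) rep(0, length(z))
  if (plane == "xz") list(cx = f, cy = zero) else list(cx = zero, cy = f)
}

#' @rdname centerline_straight
#' @export
centerline_sinusoidal <- function(amplitude_mm, period_mm, phase = 0) {
  list(cx = function(z) amplitude_mm * sin(2 * pi * z / period_mm + phase),
       cy = function(z) rep(0, length(z)))
}

#' Default vertebral-level bands
#'
#' Splits the axial extent of a grid into seven equal bands labeled C1-C7
#' (top of the grid = C1, mirroring head-to-feet slice ordering along
#' decreasing z index is not imposed; bands simply ascend with z).
#'
#' @param grid_shape Integer vector of length 3.
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @return A tibble with columns `level`, `z_min_mm`, `z_max_mm`
#'   (half-open intervals `[z_min, z_max)` in absolute mm, 0 at the lower
#'   grid face).
#' @export
default_level_boundaries <- function(grid_shape, voxel_size_mm) {
  extent <- grid_shape[3] * voxel_size_mm
  edges <- seq(0, extent, length.out = 8)
  tibble::tibble(level = paste0("C", 1:7),
                 z_min_mm = edges[1:7], z_max_mm = edges[2:8])
}

#' Specify a cord phantom
#'
#' Describes the analytic geometry and contrast of a synthetic spinal-cord
#' volume: a tube of (possibly z-varying) radius following a smooth
#' centerline, surrounded by a CSF sheath and background. Membership is by
#' in-plane (axial) distance to the centerline, so a straight segment tilted
#' by angle theta has axial cross-section area pi R^2 / cos(theta) while its
#' perpendicular cross-section stays pi R^2 — which is what slice-wise cosine
#' correction recovers.
#'
#' @param subject_id Subject label.
#' @param cord_radius_mm Cord radius in mm; a positive scalar or a function
#'   of z (mm from the axial mid-plane).
#' @param centerline A centerline as returned by [centerline_straight()] and
#'   friends.
#' @param csf_rim_mm Thickness of the CSF sheath (mm); the CSF outer radius
#'   is `cord_radius + csf_rim`.
#' @param contrast `"t1"` (cord brighter than CSF) or `"t2"` (CSF brighter).
#' @param intensities Named numeric vector `c(cord=, csf=, background=)`;
#'   defaults depend on `contrast`.
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param voxel_size_mm Isotropic voxel size (mm). The defaults used in this
#'   package are 1.0 mm ("T1w-like") and 0.8 mm ("T2w-like").
#' @param grid_shape Integer vector of length 3 (voxels).
#' @param level_boundaries Level bands as in [default_level_boundaries()].
#' @param seed Integer seed controlling the noise draw.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(subject_id = "sub-01",
                         cord_radius_mm = sqrt(70 / pi),
                         centerline = centerline_straight(),
                         csf_rim_mm = 3,
                         contrast = c("t2", "t1"),
                         intensities = NULL,
                         noise_sd = 0,
                         voxel_size_mm = 0.8,
                         grid_shape = c(48L, 48L, 48L),
                         level_boundaries = NULL,
                         seed = 1L) {
  contrast <- match.arg(contrast)
  if (is.null(intensities)) {
    intensities <- if (contrast == "t1") c(cord = 120, csf = 60, background = 20)
                   else c(cord = 60, csf = 120, background = 20)
  }
  grid_shape <- as.integer(grid_shape)
  if (is.null(level_boundaries))
    level_boundaries <- default_level_boundaries(grid_shape, voxel_size_mm)
  radius_fun <- if (is.function(cord_radius_mm)) cord_radius_mm
                else function(z) rep(cord_radius_mm, length(z))
  spec <- structure(list(
    subject_id = subject_id, radius_fun = radius_fun,
    cord_radius_mm = if (is.function(cord_radius_mm)) NA_real_ else cord_radius_mm,
    centerline = centerline, csf_rim_mm = csf_rim_mm, contrast = contrast,
    intensities = intensities, noise_sd = noise_sd,
    voxel_size_mm = voxel_size_mm, grid_shape = grid_shape,
    level_boundaries = tibble::as_tibble(level_boundaries),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  h <- spec$voxel_size_mm
  if (!is.numeric(h) || h <= 0) stop("voxel size must be positive", call. = FALSE)
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 4L))
    stop("grid_shape must be 3 integers >= 4", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (spec$csf_rim_mm <= 0) stop("csf_rim_mm must be positive", call. = FALSE)
  zc <- spec$grid_shape[3] * h / 2
  z <- voxel_centers_mm(spec$grid_shape[3], h) - zc
  R <- spec$radius_fun(z)
  if (any(!is.finite(R)) || any(R <= 0))
    stop("cord radius must be positive on every slice", call. = FALSE)
  ints <- spec$intensities
  if (spec$contrast == "t1" && ints["cord"] <= ints["csf"])
    stop("t1-like contrast requires intensity(cord) > intensity(csf)", call. = FALSE)
  if (spec$contrast == "t2" && ints["csf"] <= ints["cord"])
    stop("t2-like contrast requires intensity(csf) > intensity(cord)", call. = FALSE)
  lb <- spec$level_boundaries
  if (nrow(lb) > 1) {
    if (any(diff(lb$z_min_mm) <= 0) || any(lb$z_max_mm[-nrow(lb)] > lb$z_min_mm[-1] + 1e-9))
      stop("level boundaries must be ordered and disjoint", call. = FALSE)
  }
  if (any(lb$z_max_mm <= lb$z_min_mm))
    stop("level boundaries must have z_max > z_min", call. = FALSE)
  # centerline angle bound: keeps the axial-ellipse model valid to first order
  cx <- spec$centerline$cx(z); cy <- spec$centerline$cy(z)
  if (length(z) >= 2) {
    dz <- diff(z)
    slope <- sqrt(diff(cx)^2 + diff(cy)^2) / dz
    max_theta <- max(atan(slope)) * 180 / pi
    if (max_theta > 20 + 1e-6)
      stop(sprintf("max centerline angle %.1f deg exceeds the 20 deg limit",
                   max_theta), call. = FALSE)
  }
  # lateral containment of the cord (geometry error if the cord exits the grid)
  half_x <- spec$grid_shape[1] * h / 2
  half_y <- spec$grid_shape[2] * h / 2
  R <- R / cospi(20 / 180)  # worst-case in-plane semi-axis at the tilt limit
  if (any(abs(cx) + R > half_x - h) || any(abs(cy) + R > half_y - h))
    stop("geometry error: cord exits the grid laterally", call. = FALSE)
  invisible(spec)
}

#' Generate a phantom volume and its ground truth
#'
#' Rasterizes a [phantom_spec()] onto its voxel grid: each voxel takes the
#' cord intensity iff its in-plane distance to the centerline is at most the
#' cord radius, the CSF intensity iff within the CSF outer radius, and the
#' background intensity otherwise; independent zero-mean Gaussian noise of SD
#' `noise_sd` is then added. The same seed reproduces the volume bit for bit.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `cord_phantom` with elements
#'   * `volume`: the noisy intensity [cord_volume()];
#'   * `truth`: list with `true_mask` (binary `cord_volume`), `per_slice`
#'     (tibble: `z_index`, `z_mm`, `level`, `true_csa_mm2`, the perpendicular
#'     cross-section pi R(z)^2), `centerline` (tibble: `z_mm`, `cx_mm`,
#'     `cy_mm`, `theta_deg`), and `level_labels` (character per slice);
#'   * `spec`: the input spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$voxel_size_mm
  d <- spec$grid_shape
  xc <- d[1] * h / 2; yc <- d[2] * h / 2; zc <- d[3] * h / 2
  xs <- voxel_centers_mm(d[1], h)
  ys <- voxel_centers_mm(d[2], h)
  zs_abs <- voxel_centers_mm(d[3], h)
  zs <- zs_abs - zc
  R <- spec$radius_fun(zs)
  cx <- spec$centerline$cx(zs)
  cy <- spec$centerline$cy(zs)
  # analytic tangent angle from finite differences on a fine grid
  theta <- centerline_angle_deg(spec, zs)

  ints <- spec$intensities
  vol <- array(ints["background"], dim = d)
  mask <- array(0L, dim = d)
  r_out <- R + spec$csf_rim_mm
  # each axial slice is the axial cut of the local cylinder: an ellipse with
  # semi-axis R/cos(theta) along the in-plane tilt direction and R across it,
  # so the axial area is pi R^2 / cos(theta) and the perpendicular
  # cross-section stays pi R^2 (what the cosine correction recovers)
  ct <- cospi(theta / 180)
  eps <- 1e-4
  dcx <- (spec$centerline$cx(zs + eps) - spec$centerline$cx(zs - eps)) / (2 * eps)
  dcy <- (spec$centerline$cy(zs + eps) - spec$centerline$cy(zs - eps)) / (2 * eps)
  slope <- sqrt(dcx^2 + dcy^2)
  ux <- ifelse(slope > 1e-12, dcx / pmax(slope, 1e-12), 1)
  uy <- ifelse(slope > 1e-12, dcy / pmax(slope, 1e-12), 0)
  for (k in seq_len(d[3])) {
    wx <- xs - (xc + cx[k])
    wy <- ys - (yc + cy[k])
    # in-plane coordinates along (u) and across (v) the tilt direction
    u <- outer(wx * ux[k], wy * uy[k], `+`)
    v <- outer(wx * -uy[k], wy * ux[k], `+`)
    d2 <- (u * ct[k])^2 + v^2
    sl <- vol[, , k]
    sl[d2 <= r_out[k]^2] <- ints["csf"]
    inside <- d2 <= R[k]^2
    sl[inside] <- ints["cord"]
    vol[, , k] <- sl
    mask[, , k][inside] <- 1L
  }
  if (spec$noise_sd > 0) {
    vol <- with_seed_local(spec$seed,
      vol + array(rnorm(prod(d), 0, spec$noise_sd), dim = d))
  }
  labels <- slice_level_labels(spec$level_boundaries, zs_abs)
  per_slice <- tibble::tibble(
    z_index = seq_len(d[3]) - 1L, z_mm = zs_abs, level = labels,
    true_csa_mm2 = pi * R^2)
  truth <- list(
    true_mask = cord_volume(mask, h),
    per_slice = per_slice,
    centerline = tibble::tibble(z_mm = zs_abs, cx_mm = xc + cx, cy_mm = yc + cy,
                                theta_deg = theta),
    level_labels = labels)
  structure(list(volume = cord_volume(vol, h), truth = truth, spec = spec),
            class = "cord_phantom")
}

centerline_angle_deg <- function(spec, zs) {
  eps <- 1e-4
  dcx <- (spec$centerline$cx(zs + eps) - spec$centerline$cx(zs - eps)) / (2 * eps)
  dcy <- (spec$centerline$cy(zs + eps) - spec$centerline$cy(zs - eps)) / (2 * eps)
  atan(sqrt(dcx^2 + dcy^2)) * 180 / pi
}

slice_level_labels <- function(level_boundaries, z_abs_mm) {
  labels <- rep(NA_character_, length(z_abs_mm))
  for (i in seq_len(nrow(level_boundaries))) {
    sel <- z_abs_mm >= level_boundaries$z_min_mm[i] &
           z_abs_mm < level_boundaries$z_max_mm[i]
    labels[sel] <- level_boundaries$level[i]
  }
  labels
}

#' Specify a synthetic cohort
#'
#' Draws per-subject cord radii so that the cohort's true mean CSA has a
#' target coefficient of variation (default 10%, the order observed across
#' healthy adults). Radii are Gaussian with SD `mean_radius x cov/200`, which
#' gives a CSA COV of `cov` percent to first order (CSA is proportional to
#' radius squared). Each subject's phantom is reproducible from
#' `(seed, subject index)` alone.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param mean_csa_mm2 Cohort mean true CSA (mm^2).
#' @param csa_cov_percent Target between-subject COV of true CSA (%).
#' @param seed Master integer seed.
#' @param centerline Cord centerline shared by the cohort; the default is a
#'   gentle sinusoidal sweep (1.5 mm amplitude, 60 mm period) emulating
#'   cervical lordotic curvature.
#' @param ... Further arguments passed to [phantom_spec()] (voxel size,
#'   grid shape, contrast, noise, ...).
#' @return A list of `phantom_spec`, with a `subjects` attribute: a tibble
#'   of `subject_id`, `cord_radius_mm`, `true_csa_mm2`, `seed`.
#' @export
cohort_specs <- function(n_subjects, mean_csa_mm2 = 70, csa_cov_percent = 10,
                         seed = 1L,
                         centerline = centerline_sinusoidal(1.5, 60), ...) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  mu_r <- sqrt(mean_csa_mm2 / pi)
  sd_r <- mu_r * csa_cov_percent / 200
  if (mu_r - 6 * sd_r <= 0)
    stop("radius dispersion implies non-positive radii (COV too large)",
         call. = FALSE)
  ids <- sprintf("sub-%03d", seq_len(n_subjects))
  seeds <- vapply(seq_len(n_subjects), function(i) derive_seed(seed, i), 1L)
  radii <- vapply(seeds, function(s) with_seed_local(s, rnorm(1, mu_r, sd_r)),
                  1.0)
  if (any(radii <= 0)) stop("drawn radius not positive", call. = FALSE)
  specs <- lapply(seq_len(n_subjects), function(i)
    phantom_spec(subject_id = ids[i], cord_radius_mm = radii[i],
                 centerline = centerline, seed = seeds[i], ...))
  attr(specs, "subjects") <- tibble::tibble(
    subject_id = ids, cord_radius_mm = radii, true_csa_mm2 = pi * radii^2,
    seed = seeds)
  specs
}

#' Generate a synthetic cohort of phantoms
#'
#' @inheritParams cohort_specs
#' @return A list of [generate_phantom()] results (class `cord_cohort`), with
#'   the same `subjects` attribute as [cohort_specs()].
#' @export
generate_cohort <- function(n_subjects, mean_csa_mm2 = 70,
                            csa_cov_percent = 10, seed = 1L, ...) {
  specs <- cohort_specs(n_subjects, mean_csa_mm2, csa_cov_percent, seed, ...)
  phantoms <- lapply(specs, generate_phantom)
  attr(phantoms, "subjects") <- attr(specs, "subjects")
  class(phantoms) <- "cord_cohort"
  phantoms
}

#' Per-slice ground-truth table
#'
#' @param phantom A `cord_phantom` or `cord_cohort`.
#' @return Tibble with columns `subject`, `z`, `level`, `true_csa_mm2`
#'   (`z` is the 0-based slice index).
#' @export
truth_table <- function(phantom) {
  if (inherits(phantom, "cord_cohort"))
    return(dplyr::bind_rows(lapply(phantom, truth_table)))
  stopifnot(inherits(phantom, "cord_phantom"))
  ps <- phantom$truth$per_slice
  tibble::tibble(subject = phantom$spec$subject_id, z = ps$z_index,
                 level = ps$level, true_csa_mm2 = ps$true_csa_mm2)
}
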