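#' Per-slice mask areas
#'
#' Sums mask pixels per axial slice and multiplies by the pixel area. Empty
#' slices are flagged missing rather than reported as zero area, and are
#' later excluded from level averaging with a warning.
#'
#' @param mask A binary [cord_volume()].
#' @return Tibble with columns `z_index` (0-based), `z_mm`, `n_pixels`,
#'   `area_mm2` (NA when missing), `missing`.
#' @export
slice_areas <- function(mask) {
  stopifnot(inherits(mask, "cord_volume"))
  d <- dim(mask)
  h <- mask$voxel_size_mm
  counts <- vapply(seq_len(d[3]), function(k) sum(mask$data[, , k] != 0), 0)
  tibble::tibble(
    z_index = seq_len(d[3]) - 1L,
    z_mm = voxel_centers_mm(d[3], h),
    n_pixels = as.integer(counts),
    area_mm2 = ifelse(counts > 0, counts * h^2, NA_real_),
    missing = counts == 0)
}

#' Area of one axial slice
#'
#' @param mask A binary [cord_volume()].
#' @param z 1-based slice index.
#' @param pixel_area_mm2 Pixel area; defaults to the mask voxel size squared.
#' @return Area in mm^2, or `NA` (with a `missing` attribute) for an empty
#'   slice.
#' @export
slice_area <- function(mask, z, pixel_area_mm2 = mask$voxel_size_mm^2) {
  stopifnot(inherits(mask, "cord_volume"))
  d <- dim(mask)
  if (z < 1 || z > d[3]) stop("slice ", z, " does not exist", call. = FALSE)
  n <- sum(mask$data[, , z] != 0)
  if (n == 0) return(structure(NA_real_, missing = TRUE))
  n * pixel_area_mm2
}

#' Fit a spline-regularized centerline to a cord mask
#'
#' Computes the unweighted in-plane centroid of the mask on every populated
#' slice, regularizes `x(z)` and `y(z)` with cubic smoothing splines, and
#' derives the tangent (analytic spline derivative) and the angle `theta`
#' between the tangent and the slice normal. The first and last two
#' populated slices are flagged non-interior: spline derivatives are
#' unreliable at the ends and are excluded from angle statistics.
#'
#' @param mask A binary [cord_volume()] populated on at least 4 slices.
#' @param df Equivalent degrees of freedom of the smoothing splines;
#'   default scales with the slice count, `max(4, min(round(n/5), 15))`.
#' @return Object of class `centerline`: a tibble with columns `z_index`,
#'   `z_mm`, `cx_mm`, `cy_mm`, `dxdz`, `dydz`, `theta_deg`, `interior`.
#' @export
fit_centerline <- function(mask, df = NULL) {
  stopifnot(inherits(mask, "cord_volume"))
  d <- dim(mask)
  h <- mask$voxel_size_mm
  xs <- voxel_centers_mm(d[1], h)
  ys <- voxel_centers_mm(d[2], h)
  cent <- lapply(seq_len(d[3]), function(k) {
    sl <- mask$data[, , k] != 0
    if (!any(sl)) return(c(NA_real_, NA_real_))
    idx <- which(sl, arr.ind = TRUE)
    c(mean(xs[idx[, 1]]), mean(ys[idx[, 2]]))
  })
  cm <- do.call(rbind, cent)
  pop <- which(!is.na(cm[, 1]))
  if (length(pop) < 4)
    stop("insufficient support: centerline needs >= 4 populated slices, got ",
         length(pop), call. = FALSE)
  z <- voxel_centers_mm(d[3], h)[pop]
  if (is.null(df)) df <- select_spline_df(z, cm[pop, 1], cm[pop, 2])
  df <- min(df, length(pop) - 1)
  fx <- smooth.spline(z, cm[pop, 1], df = df)
  fy <- smooth.spline(z, cm[pop, 2], df = df)
  dx <- predict(fx, z, deriv = 1)$y
  dy <- predict(fy, z, deriv = 1)$y
  interior <- seq_along(pop) > 4 & seq_along(pop) <= length(pop) - 4
  out <- tibble::tibble(
    z_index = pop - 1L, z_mm = z,
    cx_mm = predict(fx, z)$y, cy_mm = predict(fy, z)$y,
    dxdz = dx, dydz = dy,
    theta_deg = atan(sqrt(dx^2 + dy^2)) * 180 / pi,
    interior = interior)
  class(out) <- c("centerline", class(out))
  out
}

# smoothing-spline df by AICc over both axes pooled: straight cords get the
# minimal df (derivative noise suppressed), curved cords enough df to track
# the curve without chasing centroid quantization noise
select_spline_df <- function(z, cx, cy, df_max = 15) {
  dfs <- seq(3, max(3, min(df_max, length(z) - 2)))
  n <- 2 * length(z)
  aicc <- vapply(dfs, function(df) {
    rss <- sum(c(stats::residuals(smooth.spline(z, cx, df = df)),
                 stats::residuals(smooth.spline(z, cy, df = df)))^2)
    k <- 2 * df
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }, 1.0)
  dfs[which.min(aicc)]
}

#' Cosine angle correction of an axial slice area
#'
#' Recovers the perpendicular cross-sectional area from the axial-plane
#' area when the cord centerline makes angle `theta` with the slice normal:
#' the axial cut of a tilted tube is an ellipse of area `A_perp / cos(theta)`,
#' so multiplying the measured axial area by `cos(theta)` undoes the tilt
#' bias.
#'
#' @param raw_area Axial-plane area (mm^2).
#' @param theta_deg Centerline angle in degrees, `0 <= theta < 90`.
#' @return Corrected area (mm^2).
#' @export
corrected_area <- function(raw_area, theta_deg) {
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) || any(theta_deg >= 90))
    stop("theta must lie in [0, 90)", call. = FALSE)
  raw_area * cospi(theta_deg / 180)
}

# expand a closed level range like c("C3", "C5") into C3, C4, C5
expand_levels <- function(levels, all_levels = paste0("C", 1:7)) {
  if (length(levels) == 1) return(levels)
  i <- match(levels, all_levels)
  if (any(is.na(i))) return(levels) # custom labels: use as given
  all_levels[seq(min(i), max(i))]
}

#' Mean CSA over a vertebral-level range
#'
#' Computes per-slice axial areas from a mask, applies slice-wise cosine
#' angle correction along the fitted centerline, and averages the corrected
#' areas over all slices labeled within the (closed) level range, default
#' C3-C5 included. Missing (empty) slices inside the range are excluded with
#' a warning.
#'
#' @param mask Binary [cord_volume()].
#' @param level_labels Character vector, one label per slice (NA outside the
#'   labeled extent), e.g. from a phantom's ground truth.
#' @param levels Closed level range, `c(first, last)` (default `C3`-`C5`).
#' @param centerline Optional precomputed [fit_centerline()] result.
#' @param angle_correction Apply the cosine correction (default TRUE).
#' @param subject_id,contrast,scaling_r,transform_index Provenance fields
#'   copied into the record.
#' @return One-row tibble (a CSA record): `subject_id`, `contrast`,
#'   `scaling_r`, `transform_index`, `mean_csa_mm2`, `n_slices`,
#'   `level_range`, plus a `per_slice` list-column with the corrected
#'   per-slice table.
#' @export
compute_csa <- function(mask, level_labels, levels = c("C3", "C5"),
                        centerline = NULL, angle_correction = TRUE,
                        subject_id = NA_character_, contrast = NA_character_,
                        scaling_r = NA_real_, transform_index = NA_integer_) {
  stopifnot(inherits(mask, "cord_volume"))
  d <- dim(mask)
  if (length(level_labels) != d[3])
    stop("level_labels must have one entry per slice", call. = FALSE)
  areas <- slice_areas(mask)
  areas$level <- level_labels
  wanted <- expand_levels(levels)
  areas$in_range <- !is.na(areas$level) & areas$level %in% wanted
  if (!any(areas$in_range))
    stop("no slice labeled within level range ",
         paste(levels, collapse = "-"), call. = FALSE)
  if (angle_correction) {
    if (is.null(centerline)) centerline <- fit_centerline(mask)
    areas <- dplyr::left_join(areas,
      centerline[, c("z_index", "theta_deg")], by = "z_index")
    cvec <- areas$area_mm2
    ok <- !is.na(areas$theta_deg) & !is.na(areas$area_mm2)
    cvec[ok] <- corrected_area(areas$area_mm2[ok], areas$theta_deg[ok])
    areas$corrected_mm2 <- cvec
  } else {
    areas$theta_deg <- NA_real_
    areas$corrected_mm2 <- areas$area_mm2
  }
  sel <- areas[areas$in_range, ]
  n_missing <- sum(sel$missing)
  if (n_missing > 0)
    warning(sprintf("%d empty slice(s) in level range %s excluded from CSA averaging",
                    n_missing, paste(levels, collapse = "-")), call. = FALSE)
  used <- sel[!sel$missing, ]
  if (nrow(used) == 0)
    stop("all slices in level range are empty", call. = FALSE)
  tibble::tibble(
    subject_id = subject_id, contrast = contrast, scaling_r = scaling_r,
    transform_index = transform_index,
    mean_csa_mm2 = mean(used$corrected_mm2),
    n_slices = nrow(used),
    level_range = paste(levels, collapse = "-"),
    per_slice = list(areas))
}
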