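#' Atrophy percent implied by an isotropic scaling factor
#'
#' Isotropic (homothetic) scaling of the anatomy by factor `r` shrinks every
#' cross-sectional area by `r^2`, so the simulated atrophy in percent is
#' `100 (1 - r^2)`. `scaling_for_atrophy()` is the inverse mapping,
#' `r = sqrt(1 - a / 100)`.
#'
#' @param r Scaling factor(s) in (0, 1].
#' @param atrophy_percent Atrophy percent(s) in \[0, 100).
#' @return Numeric vector.
#' @examples
#' atrophy_percent(0.93)        # 13.51
#' scaling_for_atrophy(9.75)    # 0.95
#' @export
atrophy_percent <- function(r) {
  check_scaling(r)
  100 * (1 - r^2)
}

#' @rdname atrophy_percent
#' @export
scaling_for_atrophy <- function(atrophy_percent) {
  if (any(!is.finite(atrophy_percent)) || any(atrophy_percent < 0) ||
      any(atrophy_percent >= 100))
    stop("atrophy percent must lie in [0, 100)", call. = FALSE)
  sqrt(1 - atrophy_percent / 100)
}

check_scaling <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1))
    stop("scaling factor r must lie in (0, 1]", call. = FALSE)
  invisible(r)
}

#' Axial-slice area of a disc after x-y-only scaling
#'
#' When only the in-plane (x, y) axes are scaled by `r` and the cord
#' centerline makes angle `theta` with the slice normal, the apparent
#' axial-slice area of a disc is not simply `r^2` times the original: the
#' unscaled out-of-plane radius component re-enters the axial ellipse. With
#' radius components `Rs_x = r cos(theta) R`, `Rs_z = sin(theta) R` combined
#' by the Pythagorean theorem and `Rs_y = r R`, the ellipse area becomes
#' `area * r * sqrt(r^2 cos^2(theta) + sin^2(theta))`. At `theta = 0` this
#' reduces to the isotropic result `area * r^2`; the angle dependency is the
#' reason the atrophy simulation uses isotropic scaling.
#'
#' @param area Original disc area (mm^2), positive.
#' @param r Scaling factor in (0, 1].
#' @param theta_deg Centerline angle in degrees, 0 <= theta < 90.
#' @return Scaled axial area (mm^2).
#' @examples
#' xy_scaled_area(80, 0.9, 0)   # 64.8, same as isotropic
#' xy_scaled_area(80, 0.9, 10)  # 65.03
#' @export
xy_scaled_area <- function(area, r, theta_deg) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  check_scaling(r)
  if (any(theta_deg < 0) || any(theta_deg >= 90))
    stop("theta must lie in [0, 90)", call. = FALSE)
  ct <- cospi(theta_deg / 180)
  st <- sinpi(theta_deg / 180)
  area * r * sqrt(r^2 * ct^2 + st^2)
}

#' Isotropic scaling transform about a center
#'
#' Returns the 4x4 homogeneous world-space (mm) matrix mapping
#' `p -> center + r (p - center)`. Areas of plane figures scale by `r^2`,
#' volumes by `r^3` (the determinant of the linear part).
#'
#' @param r Scaling factor in (0, 1].
#' @param center 3-vector, scaling center in mm.
#' @return 4x4 matrix of class `affine_transform` with a `provenance`
#'   attribute.
#' @export
scaling_transform <- function(r, center = c(0, 0, 0)) {
  check_scaling(r)
  stopifnot(length(center) == 3)
  m <- diag(4)
  m[1:3, 1:3] <- diag(3) * r
  m[1:3, 4] <- (1 - r) * center
  structure(m, class = c("affine_transform", "matrix", "array"),
            provenance = list(scaling_r = r, center = center))
}

rotation_matrix <- function(rot_deg) {
  cr <- cospi(rot_deg / 180); sr <- sinpi(rot_deg / 180)
  rx <- rbind(c(1, 0, 0), c(0, cr[1], -sr[1]), c(0, sr[1], cr[1]))
  ry <- rbind(c(cr[2], 0, sr[2]), c(0, 1, 0), c(-sr[2], 0, cr[2]))
  rz <- rbind(c(cr[3], -sr[3], 0), c(sr[3], cr[3], 0), c(0, 0, 1))
  rx %*% ry %*% rz  # intrinsic x-y-z convention
}

#' Rigid transform matrix from rotations and translations
#'
#' Builds the 4x4 world-space matrix of a rigid scan-rescan repositioning:
#' rotation (intrinsic x-y-z Euler angles, degrees) about `center`, followed
#' by translation. Translations are given in voxels, the units in which
#' scan-rescan repositioning bounds are specified, and converted to mm via
#' the voxel size.
#'
#' @param rot_deg Length-3 numeric, rotations about x, y, z in degrees.
#' @param trans_vox Length-3 numeric, translations in voxels.
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @param center Rotation center (mm), typically the grid center.
#' @return 4x4 `affine_transform`.
#' @export
rigid_transform <- function(rot_deg, trans_vox, voxel_size_mm,
                            center = c(0, 0, 0)) {
  stopifnot(length(rot_deg) == 3, length(trans_vox) == 3)
  rot <- rotation_matrix(rot_deg)
  m <- diag(4)
  m[1:3, 1:3] <- rot
  m[1:3, 4] <- center - rot %*% center + trans_vox * voxel_size_mm
  structure(m, class = c("affine_transform", "matrix", "array"),
            provenance = list(rot_deg = rot_deg, trans_vox = trans_vox,
                              voxel_size_mm = voxel_size_mm, center = center))
}

#' Draw random rigid scan-rescan transforms
#'
#' Components are i.i.d. continuous uniform within symmetric bounds:
#' rotations in `[-rot_bound_deg, +rot_bound_deg]` degrees about each axis
#' and translations in `[-trans_bound_vox, +trans_bound_vox]` voxels along
#' each axis (defaults +/-2.5 degrees and +/-5 voxels, 30 draws). The full
#' list is reproducible from the seed, and each draw from
#' `(seed, transform index)`.
#'
#' @param n_draws Number of Monte Carlo draws (default 30).
#' @param rot_bound_deg,trans_bound_vox Non-negative bounds.
#' @param seed Integer seed.
#' @return Tibble with columns `transform_index` (0-based), `rot_x_deg`,
#'   `rot_y_deg`, `rot_z_deg`, `trans_x_vox`, `trans_y_vox`, `trans_z_vox`,
#'   `seed`.
#' @export
sample_rigid <- function(n_draws = 30, rot_bound_deg = 2.5,
                         trans_bound_vox = 5, seed = 1L) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (rot_bound_deg < 0 || trans_bound_vox < 0)
    stop("bounds must be non-negative", call. = FALSE)
  draws <- lapply(seq_len(n_draws), function(i) {
    with_seed_local(derive_seed(seed, i), {
      r <- runif(3, -rot_bound_deg, rot_bound_deg)
      t <- runif(3, -trans_bound_vox, trans_bound_vox)
      c(r, t)
    })
  })
  m <- do.call(rbind, draws)
  tibble::tibble(
    transform_index = seq_len(n_draws) - 1L,
    rot_x_deg = m[, 1], rot_y_deg = m[, 2], rot_z_deg = m[, 3],
    trans_x_vox = m[, 4], trans_y_vox = m[, 5], trans_z_vox = m[, 6],
    seed = as.integer(seed))
}

#' Compose atrophy scaling with a rigid transform
#'
#' Builds the single world-space affine `rigid o scaling`: the anatomy is
#' first shrunk about the grid center (atrophy), then repositioned
#' (scan-rescan). Composing before resampling means only one interpolation
#' is ever applied to the image. Rotations preserve volume, so the linear
#' part's determinant is `r^3` regardless of the rigid draw.
#'
#' @param r Scaling factor in (0, 1].
#' @param rigid A single row of [sample_rigid()] (or a list with the same
#'   fields), or `NULL` for no rigid motion.
#' @param voxel_size_mm Isotropic voxel size (mm), used to convert voxel
#'   translations to mm.
#' @param center Common scaling/rotation center (mm).
#' @return 4x4 `affine_transform`.
#' @export
compose_transform <- function(r, rigid = NULL, voxel_size_mm,
                              center = c(0, 0, 0)) {
  s <- scaling_transform(r, center)
  if (is.null(rigid)) return(s)
  rg <- rigid_transform(
    rot_deg = c(rigid$rot_x_deg, rigid$rot_y_deg, rigid$rot_z_deg),
    trans_vox = c(rigid$trans_x_vox, rigid$trans_y_vox, rigid$trans_z_vox),
    voxel_size_mm = voxel_size_mm, center = center)
  m <- unclass(rg) %*% unclass(s)
  structure(m, class = c("affine_transform", "matrix", "array"),
            provenance = list(scaling_r = r,
                              transform_index = rigid$transform_index %||% NA,
                              center = center))
}

#' Resample a volume through an affine transform
#'
#' Applies a world-space affine to a volume with a single interpolation:
#' the output grid equals the input grid, each output voxel is interpolated
#' at the inverse-mapped input coordinate, and positions falling outside the
#' input field of view receive the `background` constant. Interpolation is
#' B-spline of order 0 (nearest), 1 (trilinear), 3, or 5 (default); orders
#' 3 and 5 include the exact recursive prefilter so that the interpolant
#' passes through the original samples.
#'
#' @param volume A [cord_volume()].
#' @param transform 4x4 world-space (mm) affine mapping input to output
#'   positions.
#' @param order Interpolation order, one of 0, 1, 3, 5.
#' @param background Fill value outside the field of view (default: the
#'   volume minimum).
#' @return A [cord_volume()] on the same grid.
#' @export
resample <- function(volume, transform, order = 5, background = NULL) {
  stopifnot(inherits(volume, "cord_volume"))
  m <- unclass(transform)
  if (!is.matrix(m) || any(dim(m) != c(4, 4)))
    stop("transform must be a 4x4 matrix", call. = FALSE)
  if (abs(det(m[1:3, 1:3])) < 1e-12)
    stop("transform is singular", call. = FALSE)
  if (is.null(background)) background <- min(volume$data)
  h <- volume$voxel_size_mm
  # 0-based output index -> world -> inverse transform -> 0-based input index
  idx_to_world <- diag(4); idx_to_world[1:3, 1:3] <- diag(3) * h
  idx_to_world[1:3, 4] <- h / 2
  world_to_idx <- solve(idx_to_world)
  map <- (world_to_idx %*% solve(m) %*% idx_to_world)[1:3, , drop = FALSE]
  out <- resample_affine_cpp(as.numeric(volume$data), dim(volume$data), map,
                             as.integer(order), as.numeric(background))
  cord_volume(array(out, dim = dim(volume$data)), h)
}

#' Freeze and reload Monte Carlo transform draws
#'
#' `freeze_transforms()` writes the full grid of rigid draws (one row per
#' subject x scaling x transform) to CSV with round-trip-lossless decimal
#' serialization; `load_transforms()` reads it back. Frozen runs must replay
#' even if the sampling bounds have since changed, so rows violating the
#' declared bounds load successfully with a warning (and are flagged in the
#' `bound_violation` column of the result).
#'
#' @param samples Data frame with columns `subject`, `scaling_r`,
#'   `transform_index`, `rot_x_deg`, `rot_y_deg`, `rot_z_deg`,
#'   `trans_x_vox`, `trans_y_vox`, `trans_z_vox`, `seed`.
#' @param path CSV path.
#' @param rot_bound_deg,trans_bound_vox Bounds used for the violation check
#'   on load.
#' @return `freeze_transforms()`: `path`, invisibly. `load_transforms()`:
#'   a tibble with the columns above plus `bound_violation` (logical).
#' @export
freeze_transforms <- function(samples, path) {
  cols <- transform_csv_columns()
  missing <- setdiff(cols, names(samples))
  if (length(missing))
    stop("missing transform columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- samples[cols]
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])  # round-trip lossless
  }
  readr::write_csv(out, path)
  invisible(path)
}

transform_csv_columns <- function() {
  c("subject", "scaling_r", "transform_index",
    "rot_x_deg", "rot_y_deg", "rot_z_deg",
    "trans_x_vox", "trans_y_vox", "trans_z_vox", "seed")
}

#' @rdname freeze_transforms
#' @export
load_transforms <- function(path, rot_bound_deg = 2.5, trans_bound_vox = 5) {
  # base read.csv + as.numeric: correctly-rounded strtod parsing, so the
  # %.17g serialization round-trips bit for bit
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(transform_csv_columns(), names(raw))
  if (length(missing))
    stop("transform CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  num_cols <- c("scaling_r", "rot_x_deg", "rot_y_deg", "rot_z_deg",
                "trans_x_vox", "trans_y_vox", "trans_z_vox")
  out <- tibble::as_tibble(raw)
  for (col in c(num_cols, "transform_index", "seed")) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(parsed) & !is.na(out[[col]]) & out[[col]] != "NA")
    if (length(bad))
      stop(sprintf("malformed transform CSV at line %d: expected a number in '%s', got '%s'",
                   bad[1] + 1L, col, out[[col]][bad[1]]), call. = FALSE)
    out[[col]] <- if (col %in% c("transform_index", "seed"))
      as.integer(parsed) else parsed
  }
  viol <- abs(out$rot_x_deg) > rot_bound_deg |
          abs(out$rot_y_deg) > rot_bound_deg |
          abs(out$rot_z_deg) > rot_bound_deg |
          abs(out$trans_x_vox) > trans_bound_vox |
          abs(out$trans_y_vox) > trans_bound_vox |
          abs(out$trans_z_vox) > trans_bound_vox
  if (any(viol))
    warning(sprintf("%d frozen transform(s) violate the declared bounds (+/-%g deg, +/-%g vox); replaying as stored",
                    sum(viol), rot_bound_deg, trans_bound_vox), call. = FALSE)
  out$bound_violation <- viol
  out
}
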