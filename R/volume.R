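#' Create a cord volume
#'
#' A minimal container for an isotropic 3D intensity grid: a numeric array
#' plus the voxel size in mm. The third array axis is the axial (slice)
#' direction.
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm Isotropic voxel size in mm (positive scalar).
#' @return An object of class `cord_volume`.
#' @export
cord_volume <- function(data, voxel_size_mm) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar", call. = FALSE)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "cord_volume")
}

#' @export
dim.cord_volume <- function(x) dim(x$data)

#' @export
print.cord_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cord_volume> %d x %d x %d voxels @ %g mm iso (extent %g x %g x %g mm)\n",
              d[1], d[2], d[3], x$voxel_size_mm,
              d[1] * x$voxel_size_mm, d[2] * x$voxel_size_mm,
              d[3] * x$voxel_size_mm))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

# voxel-center coordinate of 1-based indices along one axis, in mm
voxel_centers_mm <- function(n, h) (seq_len(n) - 0.5) * h

# world coordinate of the grid center
grid_center_mm <- function(vol) dim(vol) * vol$voxel_size_mm / 2

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving the isotropic voxel size in the
#' NIfTI header.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol A [cord_volume()].
#' @return `read_volume()` returns a `cord_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-6)
    stop("volume at ", path, " is not isotropic (pixdim ",
         paste(signif(pd, 6), collapse = " x "), ")", call. = FALSE)
  cord_volume(array(as.numeric(img), dim = dim(img)[1:3]), pd[1])
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cord_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- rep(vol$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Plot an axial slice of a volume
#'
#' @param object A [cord_volume()].
#' @param z Slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cord_volume <- function(object, z = NULL, ...) {
  d <- dim(object)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  h <- object$voxel_size_mm
  df <- expand.grid(x = voxel_centers_mm(d[1], h),
                    y = voxel_centers_mm(d[2], h))
  df$intensity <- as.vector(object$data[, , z])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice z = %d", z))
}
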