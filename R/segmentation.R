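#' Reference cord segmentation for phantom volumes
#'
#' A deterministic intensity-based segmenter for tube phantoms, standing in
#' for learning-based cord segmenters at desk scale. Tissue intensity modes
#' (background, cord, CSF) are estimated per volume by a 1D 3-class k-means
#' with deterministic range-based initialization, so the segmentation is
#' invariant to affine intensity rescaling. The cord is thresholded at the
#' midpoint between the cord and CSF modes — above it for t1-like contrast
#' (cord brighter than CSF), between the background/cord and cord/CSF
#' midpoints for t2-like. Each axial slice then keeps its largest 2D
#' connected component with holes filled.
#'
#' @param volume A [cord_volume()].
#' @param contrast `"t1"` or `"t2"` (decides the polarity of the cord/CSF
#'   boundary).
#' @param slices Optional integer vector of slice indices that must contain
#'   cord; if no foreground is found on any of them (default: any slice at
#'   all), a segmentation-failure error names the slices.
#' @return A binary [cord_volume()] mask with attribute `slice_counts`
#'   (integer pixels per slice).
#' @export
segment_reference <- function(volume, contrast = c("t2", "t1"),
                              slices = NULL) {
  stopifnot(inherits(volume, "cord_volume"))
  contrast <- match.arg(contrast)
  x <- as.numeric(volume$data)
  centers <- intensity_modes(x)
  if (contrast == "t1") {
    thr <- (centers[2] + centers[3]) / 2
    raw <- volume$data > thr
  } else {
    lo <- (centers[1] + centers[2]) / 2
    hi <- (centers[2] + centers[3]) / 2
    raw <- volume$data > lo & volume$data < hi
  }
  d <- dim(volume$data)
  mask <- array(0L, dim = d)
  counts <- integer(d[3])
  for (k in seq_len(d[3])) {
    sl <- clean_slice(raw[, , k])
    mask[, , k] <- sl
    counts[k] <- sum(sl)
  }
  check <- slices %||% seq_len(d[3])
  if (all(counts[check] == 0L))
    stop("segmentation failure: no cord foreground on slices ",
         paste(range(check), collapse = "-"), call. = FALSE)
  out <- cord_volume(mask, volume$voxel_size_mm)
  attr(out, "slice_counts") <- counts
  out
}

# three intensity modes (sorted ascending) as the three dominant, separated
# peaks of the intensity density. Peaks sit on the tissue plateau values and,
# unlike cluster means, do not drift with partial-volume voxels, so the
# midpoint threshold lands on the half-intensity crossing of a smoothed edge
# (the subvoxel boundary). Deterministic, and equivariant under affine
# intensity rescaling (bandwidth and separation scale with the range).
intensity_modes <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0)
    stop("segmentation failure: volume has constant intensity", call. = FALSE)
  if (length(x) > 2e5) x <- x[seq(1, length(x), length.out = 2e5)]
  bw <- diff(rng) / 128
  den <- stats::density(x, bw = bw, n = 1024,
                        from = rng[1] - 4 * bw, to = rng[2] + 4 * bw)
  y <- den$y
  is_peak <- c(FALSE, y[2:1023] > y[1:1022] & y[2:1023] >= y[3:1024], FALSE)
  is_peak <- is_peak & y > 1e-3 * max(y)  # reject numerical ripples
  px <- den$x[is_peak]
  # rank candidate peaks by surrounding mass, not raw height: a tissue
  # plateau beats the narrow overshoot ridge that high-order interpolation
  # leaves next to a sharp edge
  halfwin <- diff(rng) / 20
  mass <- vapply(px, function(p) sum(y[abs(den$x - p) < halfwin]), 1.0)
  sep <- diff(rng) / 8
  chosen <- numeric(0)
  for (i in order(-mass)) {
    if (all(abs(px[i] - chosen) >= sep)) chosen <- c(chosen, px[i])
    if (length(chosen) == 3) break
  }
  if (length(chosen) < 3)
    stop("segmentation failure: fewer than 3 intensity modes found",
         call. = FALSE)
  # refine each mode as the centroid of the top half of its density peak;
  # stabler against kernel ripple than the raw argmax
  chosen <- vapply(chosen, function(p) {
    win <- abs(den$x - p) < halfwin
    yw <- y[win]; xw <- den$x[win]
    top <- yw > 0.5 * max(yw)
    sum(xw[top] * yw[top]) / sum(yw[top])
  }, 1.0)
  chosen <- sort(chosen)
  # genuine tissue modes are separated by deep valleys; wiggles of a
  # unimodal density are not
  for (i in 1:2) {
    between <- den$x > chosen[i] & den$x < chosen[i + 1]
    pk <- min(y[which.min(abs(den$x - chosen[i]))],
              y[which.min(abs(den$x - chosen[i + 1]))])
    if (min(y[between]) > 0.5 * pk)
      stop("segmentation failure: intensity modes are not separated",
           call. = FALSE)
  }
  chosen
}

# keep the largest 2D connected component and fill its holes
clean_slice <- function(sl) {
  if (!any(sl)) return(array(0L, dim = dim(sl)))
  lab <- EBImage::bwlabel(matrix(as.numeric(sl), nrow = nrow(sl)))
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  comp <- (lab == keep)
  filled <- EBImage::fillHull(matrix(as.numeric(comp), nrow = nrow(sl)))
  array(as.integer(filled > 0), dim = dim(sl))
}

#' Run an external segmentation command
#'
#' Plug-in contract for external segmenters: any shell command that maps a
#' NIfTI volume to a binary NIfTI mask on the same grid can replace the
#' built-in reference segmenter. The command template must contain the
#' placeholders `{input}` and `{output}`.
#'
#' @param volume_path Path to the input NIfTI volume.
#' @param command Command template, e.g.
#'   `"mysegmenter --in {input} --out {output}"`.
#' @param mask_path Output mask path (default: temporary file).
#' @return The mask as a binary [cord_volume()], with attribute `mask_path`.
#' @export
run_external_segmenter <- function(volume_path, command,
                                   mask_path = tempfile(fileext = ".nii.gz")) {
  if (!file.exists(volume_path))
    stop("input volume not found: ", volume_path, call. = FALSE)
  cmd <- gsub("{input}", shQuote(volume_path),
              gsub("{output}", shQuote(mask_path), command, fixed = TRUE),
              fixed = TRUE)
  res <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop("external segmenter exited with status ", status, ":\n",
         paste(res, collapse = "\n"), call. = FALSE)
  if (!file.exists(mask_path))
    stop("external segmenter produced no output at ", mask_path, call. = FALSE)
  vol <- read_volume(volume_path)
  mask <- read_volume(mask_path)
  if (!identical(dim(mask), dim(vol)) ||
      abs(mask$voxel_size_mm - vol$voxel_size_mm) > 1e-6)
    stop(sprintf("grid mismatch: volume %s @ %g mm vs mask %s @ %g mm",
                 paste(dim(vol), collapse = "x"), vol$voxel_size_mm,
                 paste(dim(mask), collapse = "x"), mask$voxel_size_mm),
         call. = FALSE)
  vals <- unique(as.vector(mask$data))
  if (!all(vals %in% c(0, 1)))
    stop("external segmenter output is not a binary mask", call. = FALSE)
  attr(mask, "mask_path") <- mask_path
  mask
}
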