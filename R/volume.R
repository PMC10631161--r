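# Volume / Mask containers and the CT preprocessing chain:
# window (level 40, width 300) -> resample (in-plane x0.5, z to 1 mm, cubic
# for images / nearest for masks) -> min-max normalization against the
# window bounds. The order is fixed; the intensity_domain tag enforces it.

#' CT volume container
#'
#' A 3D real-valued grid indexed (x, y, z) with per-axis voxel spacing in mm
#' and an intensity-domain tag. `"HU"` marks calibrated Hounsfield units
#' (possibly windowed); `"normalized"` marks values mapped into [0, 1].
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, mm per axis, all > 0.
#' @param domain `"HU"` or `"normalized"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, domain = c("HU", "normalized")) {
  domain <- match.arg(domain)
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values (mm)")
  }
  if (domain == "normalized" && (min(data) < 0 || max(data) > 1)) {
    stop("normalized volume must have values in [0, 1]")
  }
  structure(list(data = data, spacing = spacing, domain = domain),
            class = "ct_volume")
}

#' Binary mask container
#'
#' A binary 3D grid aligned to a [ct_volume()]: ground truth or a
#' binarized prediction.
#'
#' @param data 3D array with values in \{0, 1\}.
#' @param spacing Numeric length-3, mm per axis.
#' @return An object of class `ct_mask`.
#' @export
ct_mask <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("expected 3D mask")
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(data = array(as.numeric(data), dim = dim(data)), spacing = spacing),
            class = "ct_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s, spacing %s mm, %s, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$domain, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask %s, spacing %s mm, %d foreground voxels>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

#' Read / write volumes and masks as NIfTI
#'
#' Thin wrappers around [read_nifti()] / [write_nifti()] that attach the
#' container classes. Round-trips preserve values (at float32 precision for
#' images by default) and spacing.
#'
#' @param path NIfTI file path.
#' @param domain Intensity-domain tag to attach on read.
#' @return `read_volume()` a [ct_volume()]; `read_mask()` a [ct_mask()].
#' @export
read_volume <- function(path, domain = "HU") {
  nii <- read_nifti(path)
  ct_volume(nii$data, nii$spacing, domain)
}

#' @rdname read_volume
#' @param vol A [ct_volume()].
#' @param datatype Storage type for images, see [write_nifti()].
#' @export
write_volume <- function(vol, path, datatype = "float64") {
  stopifnot(inherits(vol, "ct_volume"))
  write_nifti(vol$data, vol$spacing, path, datatype)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  nii <- read_nifti(path)
  vals <- nii$data
  if (!all(vals %in% c(0, 1))) stop("mask file contains non-binary values: ", path)
  ct_mask(vals, nii$spacing)
}

#' @rdname read_volume
#' @param mask A [ct_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ct_mask"))
  write_nifti(mask$data, mask$spacing, path, "uint8")
}

#' Intensity windowing
#'
#' Clips Hounsfield intensities to the window `[level - width/2,
#' level + width/2]`; the soft-tissue defaults 40/300 give [-110, 190] HU.
#' Idempotent; the intensity domain stays HU.
#'
#' @param vol A [ct_volume()] in the HU domain.
#' @param level Window level (center), HU.
#' @param width Window width, HU; must be positive.
#' @return A windowed [ct_volume()].
#' @export
apply_window <- function(vol, level = 40, width = 300) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$domain != "HU") stop("windowing applies to HU-domain volumes")
  if (width <= 0) stop("window width must be positive")
  lo <- level - width / 2
  hi <- level + width / 2
  vol$data <- pmin(pmax(vol$data, lo), hi)
  vol
}

#' Min-max normalization against the window bounds
#'
#' Maps the window range `[level - width/2, level + width/2]` linearly to
#' [0, 1] and tags the volume `normalized`. Normalizing against the fixed
#' window bounds (rather than the per-volume min/max) keeps intensities
#' comparable across cases.
#'
#' @inheritParams apply_window
#' @return A normalized [ct_volume()].
#' @export
normalize_volume <- function(vol, level = 40, width = 300) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$domain != "HU") stop("volume is already normalized")
  if (width <= 0) stop("window width must be positive")
  lo <- level - width / 2
  x <- (vol$data - lo) / width
  if (min(vol$data) == max(vol$data)) {
    warning("constant volume: normalization maps it by the window bounds")
  }
  vol$data <- pmin(pmax(x, 0), 1)
  vol$domain <- "normalized"
  vol
}

#' Output grid of the resampling step
#'
#' In-plane dimensions are scaled by `inplane_factor` (spacing divided by
#' it); the z axis is resampled to `target_z_spacing` using the grid-point
#' convention `n_out = round((n_in - 1) * s_in / s_out) + 1`. The canonical
#' 512 x 512 x 101 case at (0.7, 0.7, 1.5) mm becomes 256 x 256 x 151 at
#' (1.4, 1.4, 1.0) mm.
#'
#' @param dims Integer length-3 input grid.
#' @param spacing Numeric length-3 input spacing, mm.
#' @param inplane_factor Scale on the x and y grid sizes (default 0.5).
#' @param target_z_spacing Output z spacing, mm (default 1).
#' @return List with `dims` and `spacing` of the output grid.
#' @export
resampled_dims <- function(dims, spacing, inplane_factor = 0.5,
                           target_z_spacing = 1.0) {
  stopifnot(length(dims) == 3L, length(spacing) == 3L,
            inplane_factor > 0, target_z_spacing > 0)
  nx <- as.integer(round(dims[1] * inplane_factor))
  ny <- as.integer(round(dims[2] * inplane_factor))
  nz <- as.integer(round((dims[3] - 1) * spacing[3] / target_z_spacing)) + 1L
  list(dims = c(nx, ny, nz),
       spacing = c(spacing[1] / inplane_factor, spacing[2] / inplane_factor,
                   target_z_spacing))
}

# Keys cubic-convolution weights (a = -0.5) for the 4 taps at floor(u)-1 ..
# floor(u)+2; exact interpolation at grid points (t = 0 -> 0,1,0,0).
cubic_weights <- function(t) {
  cbind(((-t + 2) * t - 1) * t / 2,
        ((3 * t - 5) * t * t + 2) / 2,
        ((-3 * t + 4) * t + 1) * t / 2,
        (t - 1) * t * t / 2)
}

# Dense 1D interpolation operator mapping n_in grid samples to coordinates
# u (0-based, input grid units). Taps outside the grid are clamped to the
# edge sample (replicate padding).
interp_matrix_1d <- function(n_in, u, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  n_out <- length(u)
  A <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(round(u), 0), n_in - 1) + 1L
    A[cbind(seq_len(n_out), idx)] <- 1
    return(A)
  }
  base <- floor(u)
  t <- u - base
  W <- cubic_weights(t)
  for (k in 0:3) {
    idx <- pmin(pmax(base - 1 + k, 0), n_in - 1) + 1L
    A[cbind(seq_len(n_out), idx)] <- A[cbind(seq_len(n_out), idx)] + W[, k + 1]
  }
  A
}

# Apply a 1D operator along one axis of a 3D array.
apply_axis <- function(arr, A, axis) {
  d <- dim(arr)
  if (axis == 1L) {
    out <- A %*% matrix(arr, d[1], d[2] * d[3])
    return(array(out, c(nrow(A), d[2], d[3])))
  }
  perm <- if (axis == 2L) c(2L, 1L, 3L) else c(3L, 1L, 2L)
  x <- aperm(arr, perm)
  dp <- dim(x)
  out <- array(A %*% matrix(x, dp[1], dp[2] * dp[3]), c(nrow(A), dp[2], dp[3]))
  aperm(out, order(perm))
}

#' Resample a volume or mask to the training grid
#'
#' Scales the in-plane grid by `inplane_factor` and resamples the z axis to
#' `target_z_spacing` mm. Images use separable cubic (Keys) interpolation;
#' masks use nearest-neighbour so the output stays binary.
#'
#' @param vol A [ct_volume()] or [ct_mask()].
#' @param inplane_factor Scale on the x/y grid sizes (default 0.5; output
#'   spacing is divided by it).
#' @param target_z_spacing Output z spacing in mm (default 1).
#' @return The resampled object, same class as the input.
#' @export
resample_volume <- function(vol, inplane_factor = 0.5, target_z_spacing = 1.0) {
  is_mask <- inherits(vol, "ct_mask")
  if (!is_mask && !inherits(vol, "ct_volume")) stop("expected ct_volume or ct_mask")
  d <- dim(vol$data)
  out <- resampled_dims(d, vol$spacing, inplane_factor, target_z_spacing)
  if (any(out$dims < 8L)) {
    stop("resampled dimension below 8 voxels (",
         paste(out$dims, collapse = "x"), "); refusing to proceed")
  }
  method <- if (is_mask) "nearest" else "cubic"
  # output grid point i sits at physical i * s_out, i.e. input coordinate
  # i * s_out / s_in (0-based, origin-aligned grids)
  arr <- vol$data
  for (ax in 1:3) {
    if (out$dims[ax] == d[ax] && abs(out$spacing[ax] - vol$spacing[ax]) < 1e-12) next
    u <- (0:(out$dims[ax] - 1)) * out$spacing[ax] / vol$spacing[ax]
    A <- interp_matrix_1d(d[ax], u, method)
    arr <- apply_axis(arr, A, ax)
  }
  if (is_mask) {
    arr <- array(as.numeric(arr > 0.5), dim = dim(arr))
    ct_mask(arr, out$spacing)
  } else {
    vol$data <- arr
    vol$spacing <- out$spacing
    vol
  }
}

#' Full preprocessing chain
#'
#' For images: window -> resample -> normalize, in that order. For masks the
#' window/normalize steps do not apply; only the (nearest-neighbour)
#' resampling runs, so image and mask stay on a common grid.
#'
#' @param x A [ct_volume()] (HU domain) or [ct_mask()].
#' @param level,width Window parameters, HU.
#' @param inplane_factor,target_z_spacing Resampling parameters.
#' @return The preprocessed object; images come back `normalized` in [0, 1]
#'   with z spacing `target_z_spacing`.
#' @export
preprocess <- function(x, level = 40, width = 300, inplane_factor = 0.5,
                       target_z_spacing = 1.0) {
  UseMethod("preprocess")
}

#' @export
preprocess.ct_volume <- function(x, level = 40, width = 300,
                                 inplane_factor = 0.5, target_z_spacing = 1.0) {
  x <- apply_window(x, level, width)
  x <- resample_volume(x, inplane_factor, target_z_spacing)
  # cubic interpolation can overshoot the window bounds slightly; the
  # normalization clamp restores [0, 1]
  normalize_volume(x, level, width)
}

#' @export
preprocess.ct_mask <- function(x, level = 40, width = 300,
                               inplane_factor = 0.5, target_z_spacing = 1.0) {
  resample_volume(x, inplane_factor, target_z_spacing)
}
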