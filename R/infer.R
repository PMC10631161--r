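# Whole-volume inference: the network sees fixed-depth slabs, so a full CT
# volume is tiled along z, each slab predicted, and overlapping predictions
# averaged. The final slab is end-aligned (no synthetic slices enter the
# network); short volumes are zero-padded symmetrically and cropped back.

#' Predict a whole volume slab-wise
#'
#' Tiles the z axis into slabs of `slab_depth` slices with stride
#' `slab_depth - overlap`, appending an end-aligned final slab when the
#' stride does not cover the last slices; overlapping predictions are
#' averaged. `model` may also be a function mapping a slab array to a
#' probability array (used for stitching tests).
#'
#' @param model A `dst_net` (or a function for testing).
#' @param vol Preprocessed (normalized) [ct_volume()], in-plane dims
#'   divisible by 16 and matching the model's configured (W, H).
#' @param slab_depth Slices per slab (divisible by 16).
#' @param overlap Slices shared by consecutive slabs (0 <= overlap <
#'   slab_depth).
#' @return A [ct_volume()] of foreground probabilities on the input grid.
#' @export
predict_volume <- function(model, vol, slab_depth = 32L, overlap = 0L) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$domain != "normalized") stop("volume must be preprocessed (normalized) first")
  if (slab_depth %% 16L != 0L) stop("slab_depth must be divisible by 16")
  if (overlap < 0 || overlap >= slab_depth) stop("need 0 <= overlap < slab_depth")
  d <- dim(vol$data)
  if (any(d[1:2] %% 16L != 0L)) {
    stop("in-plane dims ", paste(d[1:2], collapse = "x"),
         " are not divisible by 16; pad or crop the volume first")
  }
  fwd <- if (is.function(model)) model else function(slab) net_forward(model, slab)

  D <- d[3]
  if (D < slab_depth) {
    pad <- slab_depth - D
    lo <- pad %/% 2L
    padded <- array(0, c(d[1:2], slab_depth))
    padded[, , (lo + 1L):(lo + D)] <- vol$data
    prob <- fwd(padded)[, , (lo + 1L):(lo + D), drop = FALSE]
    return(ct_volume(prob, vol$spacing, "normalized"))
  }

  starts <- seq(1L, D - slab_depth + 1L, by = slab_depth - overlap)
  if (starts[length(starts)] + slab_depth - 1L < D) {
    starts <- c(starts, D - slab_depth + 1L)   # end-aligned final slab
  }
  acc <- array(0, d)
  cnt <- array(0, d)
  for (s in starts) {
    zi <- s:(s + slab_depth - 1L)
    acc[, , zi] <- acc[, , zi] + fwd(vol$data[, , zi, drop = FALSE])
    cnt[, , zi] <- cnt[, , zi] + 1
  }
  ct_volume(acc / cnt, vol$spacing, "normalized")
}

#' Threshold probabilities into a mask
#'
#' Strict-greater thresholding: a voxel is foreground iff its probability
#' exceeds `threshold`; ties go to background, consistent with the
#' background-dominant prior (tumors occupy ~0.267% of the volume).
#'
#' @param prob Probability [ct_volume()] (or array in [0, 1]).
#' @param threshold In [0, 1] (default 0.5).
#' @param spacing Spacing when `prob` is a plain array.
#' @return A [ct_mask()].
#' @export
binarize <- function(prob, threshold = 0.5, spacing = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (inherits(prob, "ct_volume")) {
    spacing <- prob$spacing
    prob <- prob$data
  }
  if (min(prob) < 0 || max(prob) > 1) stop("probabilities must lie in [0, 1]")
  ct_mask(array(as.numeric(prob > threshold), dim = dim(prob)),
          spacing %||% c(1, 1, 1))
}

#' Export one slice of a probability map as a heat map
#'
#' Writes a PNG of the axial slice with a cold-to-red colormap: the closer
#' to red, the more the model leans toward tumor tissue at that location.
#'
#' @param prob Probability [ct_volume()] or 3D array.
#' @param slice_index Axial slice (1-based).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(prob, slice_index, path) {
  if (inherits(prob, "ct_volume")) prob <- prob$data
  d <- dim(prob)
  if (slice_index < 1 || slice_index > d[3]) {
    stop("slice index ", slice_index, " out of range [1, ", d[3], "]")
  }
  sl <- prob[, , slice_index]
  pal <- grDevices::colorRampPalette(c("#00004b", "#0050ff", "#00e0e0",
                                       "#ffff00", "#ff0000"))(256)
  grDevices::png(path, width = d[1], height = d[2])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(seq_len(d[1]), seq_len(d[2]), sl, zlim = c(0, 1), col = pal,
                  axes = FALSE, xlab = "", ylab = "", useRaster = TRUE)
  invisible(path)
}
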