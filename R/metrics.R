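# The five evaluation metrics: volume-overlap (Dice, IoU), surface-distance
# (Hausdorff, directed average surface distance) and voxelwise mean absolute
# error. Surface metrics work on 6-connectivity boundary voxel centers in
# physical mm (voxel units optional via unit spacing).

check_same_grid <- function(x, y) {
  if (!identical(dim(x$data), dim(y$data))) {
    stop("masks are on different grids: ", paste(dim(x$data), collapse = "x"),
         " vs ", paste(dim(y$data), collapse = "x"))
  }
}

as_mask <- function(m, spacing = c(1, 1, 1)) {
  if (inherits(m, "ct_mask")) m else ct_mask(m, spacing)
}

#' Dice score coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)`. Two empty masks agree perfectly and
#' score 1.
#'
#' @param x,y Binary masks ([ct_mask()] or plain binary 3D arrays on the
#'   same grid).
#' @return Dice in [0, 1].
#' @export
dice <- function(x, y) {
  x <- as_mask(x); y <- as_mask(y)
  check_same_grid(x, y)
  sx <- sum(x$data); sy <- sum(y$data)
  if (sx + sy == 0) return(1)
  2 * sum(x$data * y$data) / (sx + sy)
}

#' Intersection over union
#'
#' `|X intersect Y| / |X union Y|`; 1 when both masks are empty.
#'
#' @inheritParams dice
#' @return IoU in [0, 1].
#' @export
iou <- function(x, y) {
  x <- as_mask(x); y <- as_mask(y)
  check_same_grid(x, y)
  inter <- sum(x$data * y$data)
  uni <- sum(pmax(x$data, y$data))
  if (uni == 0) return(1)
  inter / uni
}

#' Mean absolute voxelwise error
#'
#' Mean over all grid voxels of `|truth - prediction|` for binarized masks:
#' the mislabeled-voxel fraction. With tumors near 0.267% of the volume the
#' magnitudes are naturally of order 1e-3 and below.
#'
#' @inheritParams dice
#' @return MAE in [0, 1].
#' @export
mae <- function(x, y) {
  x <- as_mask(x); y <- as_mask(y)
  check_same_grid(x, y)
  mean(abs(x$data - y$data))
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one 6-neighbour background voxel
#' (out-of-grid counts as background), returned as voxel-center coordinates
#' in physical mm (`(index - 1) * spacing` per axis).
#'
#' @param mask A [ct_mask()] (or binary array; unit spacing assumed).
#' @return Numeric matrix n x 3 of mm coordinates (0 rows for an empty mask).
#' @export
surface_voxels <- function(mask) {
  mask <- as_mask(mask)
  m <- mask$data
  d <- dim(m)
  pad_shift <- function(arr, ax, k) {
    idx <- seq_len(d[ax]) + k
    out <- array(0, d)
    src <- idx >= 1 & idx <= d[ax]
    if (!any(src)) return(out)
    if (ax == 1) out[src, , ] <- arr[idx[src], , ]
    else if (ax == 2) out[, src, ] <- arr[, idx[src], ]
    else out[, , src] <- arr[, , idx[src]]
    out
  }
  n_fg_neighbors <- array(0, d)
  for (ax in 1:3) for (k in c(-1L, 1L)) {
    n_fg_neighbors <- n_fg_neighbors + pad_shift(m, ax, k)
  }
  surf <- which(m > 0 & n_fg_neighbors < 6)
  if (length(surf) == 0) return(matrix(0, 0, 3))
  idx <- arrayInd(surf, d)
  sweep(idx - 1, 2, mask$spacing, `*`)
}

# Directed minimal distances: for each row of a, min Euclidean distance to
# the rows of b. Chunked so the cross-distance matrix stays small.
directed_min_dists <- function(a, b, chunk = 1024L) {
  sq_b <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a))
    ablk <- a[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(ablk^2), sq_b, `+`) - 2 * tcrossprod(ablk, b)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Hausdorff distance between two point sets
#'
#' `H(A, B) = max(h(A, B), h(B, A))` with `h(A, B)` the maximum over A of
#' the minimal Euclidean distance to B.
#'
#' @param a,b Non-empty numeric matrices (points in rows, mm).
#' @return The symmetric Hausdorff distance.
#' @export
hausdorff <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("Hausdorff distance is undefined for an empty point set")
  }
  max(max(directed_min_dists(a, b)), max(directed_min_dists(b, a)))
}

#' Average surface distance (directed)
#'
#' Mean over the points of `x` of the minimal distance to `y` - directed
#' (prediction -> truth) as printed; `symmetric = TRUE` averages both
#' directions over the pooled points, the convention most toolkits use.
#'
#' @param x,y Non-empty numeric point matrices (mm).
#' @param symmetric Average both directions (default `FALSE`).
#' @return The average surface distance.
#' @export
asd <- function(x, y, symmetric = FALSE) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    stop("average surface distance is undefined for an empty point set")
  }
  dxy <- directed_min_dists(x, y)
  if (!symmetric) return(mean(dxy))
  dyx <- directed_min_dists(y, x)
  (sum(dxy) + sum(dyx)) / (length(dxy) + length(dyx))
}

#' Evaluate one case: all five metrics
#'
#' Computes Dice, IoU, Hausdorff distance, ASD (directed, prediction surface
#' to truth surface) and MAE for a predicted mask against ground truth.
#' Surface metrics use boundary voxel centers in mm (or voxel units with
#' `units = "voxel"`). When either mask is empty the surface metrics are
#' undefined and reported `NA` with a warning; the overlap metrics are still
#' computed.
#'
#' @param pred,truth Binary masks on the same grid.
#' @param spacing Voxel spacing (defaults to the masks' spacing).
#' @param units `"mm"` or `"voxel"`.
#' @param case_id Optional identifier carried into the result.
#' @return A one-row `data.frame`: `case`, `dsc`, `iou`, `hausdorff`,
#'   `asd`, `mae`.
#' @export
evaluate_case <- function(pred, truth, spacing = NULL, units = c("mm", "voxel"),
                          case_id = NA) {
  units <- match.arg(units)
  if (!inherits(pred, "ct_mask")) pred <- ct_mask(pred, spacing %||% c(1, 1, 1))
  if (!inherits(truth, "ct_mask")) truth <- ct_mask(truth, spacing %||% c(1, 1, 1))
  check_same_grid(pred, truth)
  if (units == "voxel") {
    pred$spacing <- c(1, 1, 1)
    truth$spacing <- c(1, 1, 1)
  } else if (!is.null(spacing)) {
    pred$spacing <- spacing
    truth$spacing <- spacing
  }
  hd <- sd_ <- NA_real_
  if (sum(pred$data) > 0 && sum(truth$data) > 0) {
    sp <- surface_voxels(pred)
    st <- surface_voxels(truth)
    hd <- hausdorff(sp, st)
    sd_ <- asd(sp, st)
  } else {
    warning("empty mask: surface metrics are undefined for this case")
  }
  data.frame(case = case_id, dsc = dice(pred, truth), iou = iou(pred, truth),
             hausdorff = hd, asd = sd_, mae = mae(pred, truth))
}

#' Evaluate many cases and aggregate
#'
#' @param preds,truths Lists of masks, element-wise aligned.
#' @param units Distance units, see [evaluate_case()].
#' @return List with `per_case` (data frame) and `mean` (named means of the
#'   five metrics, `NA` surface values removed).
#' @export
evaluate_cases <- function(preds, truths, units = "mm") {
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  per <- do.call(rbind, lapply(seq_along(preds), function(i) {
    evaluate_case(preds[[i]], truths[[i]], units = units, case_id = i)
  }))
  means <- vapply(c("dsc", "iou", "hausdorff", "asd", "mae"),
                  function(cl) mean(per[[cl]], na.rm = TRUE), numeric(1))
  list(per_case = per, mean = means)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
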