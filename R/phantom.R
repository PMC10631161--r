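# Synthetic abdominal-CT phantoms with adrenal-style tumors.
#
# The stated world: soft-tissue background around 40 HU (sd 12), two
# kidney-like organs at 100 HU, ellipsoidal tumors at 70 +/- 15 HU with a
# smoothly varying interior, blurred contours, long axis >= 10 mm, and a
# cohort in which ~27% of cases (49/182) are bilateral and tumors occupy
# ~0.267% of the voxels on average. Grids default to 96 x 96 x D voxels at
# (1, 1, 1.5) mm with D varying per case (40-100 slices).

#' Phantom specification
#'
#' Describes one synthetic case: grid and spacing, background/organ/tumor
#' intensity model, tumor geometry (per-tumor ellipsoid semi-axes in mm),
#' contour blur, and the RNG seed. Bilateral cases (`n_tumors = 2`) place
#' the tumors mirror-symmetrically about the mid-sagittal plane, above the
#' superomedial pole of each kidney-like organ.
#'
#' @param grid_size Integer length-3 (W, H, D), voxels.
#' @param spacing Numeric length-3, mm.
#' @param background_hu Mean soft-tissue intensity, HU.
#' @param noise_sd Additive Gaussian noise sd, HU.
#' @param n_tumors 1 (unilateral) or 2 (bilateral).
#' @param tumor_axes_mm Numeric matrix `n_tumors` x 3 of ellipsoid
#'   semi-axes in mm (a vector is accepted for one tumor). Every tumor must
#'   have long axis `2 * max(semi-axes) >= 10` mm.
#' @param tumor_hu_mean,tumor_hu_sd Tumor interior intensity model, HU.
#' @param edge_blur_sigma_mm Gaussian blur applied to the composited image
#'   to soften contours, mm (0 disables).
#' @param organ_params List of two organ descriptors, each
#'   `list(center_mm, axes_mm, hu)`; `NULL` places defaults from the grid.
#' @param seed Integer RNG seed for this case.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(96L, 96L, 64L),
                         spacing = c(1.0, 1.0, 1.5),
                         background_hu = 40, noise_sd = 12,
                         n_tumors = 1L,
                         tumor_axes_mm = NULL,
                         tumor_hu_mean = 70, tumor_hu_sd = 15,
                         edge_blur_sigma_mm = 1.5,
                         organ_params = NULL,
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 3L || any(grid_size <= 0)) stop("grid_size must be 3 positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (!n_tumors %in% c(1L, 2L)) stop("n_tumors must be 1 or 2")
  if (is.null(tumor_axes_mm)) {
    tumor_axes_mm <- matrix(rep(c(9, 7, 8), n_tumors), ncol = 3, byrow = TRUE)
  }
  if (is.null(dim(tumor_axes_mm))) tumor_axes_mm <- matrix(tumor_axes_mm, ncol = 3)
  if (nrow(tumor_axes_mm) != n_tumors) stop("tumor_axes_mm must have one row per tumor")
  long_axes <- 2 * apply(tumor_axes_mm, 1, max)
  if (any(long_axes < 10 - 1e-9)) {
    stop("tumor long axis ", paste(signif(long_axes[long_axes < 10], 3), collapse = ", "),
         " mm is below the 10 mm inclusion threshold")
  }
  extent <- (grid_size - 1) * spacing
  if (is.null(organ_params)) {
    axes <- c(0.13, 0.11, 0.18) * min(extent[1], extent[3]) / 0.9
    axes <- pmin(axes, extent * 0.22)
    organ_params <- list(
      list(center_mm = c(0.30, 0.58, 0.40) * extent, axes_mm = axes, hu = 100),
      list(center_mm = c(0.70, 0.58, 0.40) * extent, axes_mm = axes, hu = 100))
  }
  spec <- structure(list(
    grid_size = grid_size, spacing = spacing, background_hu = background_hu,
    noise_sd = noise_sd, n_tumors = as.integer(n_tumors),
    tumor_axes_mm = tumor_axes_mm, tumor_hu_mean = tumor_hu_mean,
    tumor_hu_sd = tumor_hu_sd, edge_blur_sigma_mm = edge_blur_sigma_mm,
    organ_params = organ_params, seed = as.integer(seed)),
    class = "phantom_spec")
  spec$tumor_centers_mm <- tumor_centers(spec)
  validate_phantom_spec(spec)
  spec
}

# Adrenal position: superomedial to each kidney-like organ. Mirror-symmetric
# about the mid-sagittal plane for bilateral cases.
tumor_centers <- function(spec) {
  extent <- (spec$grid_size - 1) * spec$spacing
  centers <- matrix(0, spec$n_tumors, 3)
  for (i in seq_len(spec$n_tumors)) {
    org <- spec$organ_params[[i]]
    medial <- if (org$center_mm[1] < extent[1] / 2) 1 else -1
    long_sa <- max(spec$tumor_axes_mm[i, ])
    centers[i, ] <- org$center_mm +
      c(medial * (org$axes_mm[1] * 0.4), -org$axes_mm[2] * 0.3,
        org$axes_mm[3] + long_sa * 0.9)
    centers[i, ] <- pmin(pmax(centers[i, ], spec$tumor_axes_mm[i, ] + spec$spacing),
                         extent - spec$tumor_axes_mm[i, ] - spec$spacing)
  }
  centers
}

validate_phantom_spec <- function(spec) {
  extent <- (spec$grid_size - 1) * spec$spacing
  for (i in seq_len(spec$n_tumors)) {
    lo <- spec$tumor_centers_mm[i, ] - spec$tumor_axes_mm[i, ]
    hi <- spec$tumor_centers_mm[i, ] + spec$tumor_axes_mm[i, ]
    if (any(lo < 0) || any(hi > extent)) {
      stop("tumor ", i, " extends outside the image grid (bounding box ",
           paste(signif(lo, 3), collapse = ","), " to ",
           paste(signif(hi, 3), collapse = ","), " mm, grid extent ",
           paste(signif(extent, 3), collapse = ","), " mm)")
    }
  }
  if (spec$n_tumors == 2L) {
    d <- sqrt(sum((spec$tumor_centers_mm[1, ] - spec$tumor_centers_mm[2, ])^2))
    if (d <= max(spec$tumor_axes_mm[1, ]) + max(spec$tumor_axes_mm[2, ])) {
      stop("bilateral tumors overlap (center distance ", signif(d, 3), " mm)")
    }
  }
  invisible(spec)
}

# Voxel-center mm coordinate vectors for a grid.
grid_coords <- function(grid_size, spacing) {
  lapply(1:3, function(a) (0:(grid_size[a] - 1)) * spacing[a])
}

# Indicator array of an analytic ellipsoid (voxel-center test).
ellipsoid_mask <- function(grid_size, spacing, center_mm, axes_mm) {
  co <- grid_coords(grid_size, spacing)
  qx <- ((co[[1]] - center_mm[1]) / axes_mm[1])^2
  qy <- ((co[[2]] - center_mm[2]) / axes_mm[2])^2
  qz <- ((co[[3]] - center_mm[3]) / axes_mm[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  array(as.numeric(q <= 1), dim = grid_size)
}

# Separable Gaussian blur with replicate edge handling; sigma in voxels per
# axis. Implemented as shifted weighted sums (truncated at 3 sigma).
gaussian_blur3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- dnorm(-r:r, sd = s)
    arr <- blur1d_cpp(arr, w / sum(w), ax)
  }
  arr
}

#' Generate one phantom case
#'
#' Composites background, two kidney-like organs and the tumor ellipsoids
#' (heterogeneous interior: a Gaussian random field smoothed at 2 mm),
#' blurs the image contours, adds acquisition noise, and returns the image
#' together with the clean analytic tumor mask. Deterministic given
#' `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_case`: `image` ([ct_volume()], HU),
#'   `mask` ([ct_mask()]), `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  gs <- spec$grid_size
  sp <- spec$spacing
  img <- array(spec$background_hu, dim = gs)
  for (org in spec$organ_params) {
    inside <- ellipsoid_mask(gs, sp, org$center_mm, org$axes_mm) > 0
    img[inside] <- org$hu
  }

  mask <- array(0, dim = gs)
  for (i in seq_len(spec$n_tumors)) {
    tm <- ellipsoid_mask(gs, sp, spec$tumor_centers_mm[i, ], spec$tumor_axes_mm[i, ])
    if (any(tm > 0 & mask > 0)) stop("tumors overlap in the voxel grid")
    mask <- pmax(mask, tm)
  }
  inside <- mask > 0
  if (spec$tumor_hu_sd > 0) {
    # heterogeneous interior: white noise smoothed at 2 mm, built on the
    # tumors' bounding box only (identical model, far cheaper per case)
    idx <- which(inside, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - 3L, 1L)
    hi <- pmin(apply(idx, 2, max) + 3L, gs)
    bb <- hi - lo + 1L
    field <- array(rnorm(prod(bb)), dim = bb)
    field <- gaussian_blur3(field, 2.0 / sp)
    field <- field / stats::sd(field)
    box <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    in_box <- inside[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    box[in_box] <- spec$tumor_hu_mean + spec$tumor_hu_sd * field[in_box]
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- box
  } else {
    img[inside] <- spec$tumor_hu_mean
  }

  if (spec$edge_blur_sigma_mm > 0) {
    img <- gaussian_blur3(img, spec$edge_blur_sigma_mm / sp)
  }
  if (spec$noise_sd > 0) {
    img <- img + array(rnorm(prod(gs), sd = spec$noise_sd), dim = gs)
  }
  structure(list(image = ct_volume(img, sp, "HU"),
                 mask = ct_mask(mask, sp),
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s, %d tumor(s), %.4g%% tumor voxels, seed %d>\n",
              paste(x$spec$grid_size, collapse = "x"), x$spec$n_tumors,
              100 * mean(x$mask$data), x$spec$seed))
  invisible(x)
}

# Sample per-tumor semi-axes whose total analytic volume is close to
# target_mm3, with mild anisotropy, honouring the >= 10 mm long axis rule.
sample_tumor_axes <- function(n_tumors, target_mm3) {
  shares <- if (n_tumors == 2L) {
    s <- runif(1, 0.35, 0.65); c(s, 1 - s)
  } else 1
  axes <- matrix(0, n_tumors, 3)
  for (i in seq_len(n_tumors)) {
    v <- target_mm3 * shares[i]
    r <- (3 * v / (4 * pi))^(1 / 3)
    ratio <- exp(rnorm(3, sd = 0.18))
    ratio <- ratio / prod(ratio)^(1 / 3)   # volume-preserving anisotropy
    ax <- r * ratio
    if (2 * max(ax) < 10) ax <- ax * (10 / (2 * max(ax)))  # inclusion rule
    axes[i, ] <- ax
  }
  axes
}

#' Generate a cohort of phantom cases
#'
#' Samples per-case specifications so that the expected bilateral share and
#' the expected tumor voxel fraction match their targets, with slice count
#' varying uniformly between `d_range[1]` and `d_range[2]` per case. Each
#' case draws from its own RNG stream derived from `(seed, case index)`, so
#' the cohort is reproducible case by case.
#'
#' @param n_cases Number of cases (>= 1).
#' @param bilateral_fraction Expected share of bilateral cases; the source
#'   cohort ratio 49/182 by default.
#' @param volume_fraction_target Expected per-case tumor voxel fraction
#'   (default 0.00267); must lie in (0, 0.05).
#' @param seed Cohort seed.
#' @param grid_wh In-plane grid size, voxels.
#' @param d_range Inclusive slice-count range.
#' @param spacing Voxel spacing, mm.
#' @return List of [make_phantom()] cases.
#' @export
make_cohort <- function(n_cases, bilateral_fraction = 49 / 182,
                        volume_fraction_target = 0.00267, seed = 1000L,
                        grid_wh = 96L, d_range = c(40L, 100L),
                        spacing = c(1.0, 1.0, 1.5)) {
  if (n_cases < 1) stop("n_cases must be at least 1")
  if (bilateral_fraction < 0 || bilateral_fraction > 1) stop("bilateral_fraction must be in [0, 1]")
  if (volume_fraction_target <= 0 || volume_fraction_target >= 0.05) {
    stop("volume_fraction_target must be in (0, 0.05)")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  lapply(seq_len(n_cases), function(i) {
    case_seed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    set.seed(case_seed)
    d_choices <- d_range[1]:d_range[2]
    d <- d_choices[sample.int(length(d_choices), 1L)]
    gs <- c(grid_wh, grid_wh, d)
    n_tumors <- if (runif(1) < bilateral_fraction) 2L else 1L
    vol_mm3 <- prod(gs) * prod(spacing)
    # mild lognormal size jitter, mean-corrected so E[fraction] stays on target
    jitter <- exp(rnorm(1, sd = 0.2) - 0.02)
    target <- volume_fraction_target * vol_mm3 * jitter
    axes <- sample_tumor_axes(n_tumors, target)
    spec <- phantom_spec(grid_size = gs, spacing = spacing,
                         n_tumors = n_tumors, tumor_axes_mm = axes,
                         seed = case_seed)
    make_phantom(spec)
  })
}

#' Connected components of a binary 3D array
#'
#' Labels foreground components under 6-, 18- or 26-connectivity
#' (breadth-first search). Used for laterality counts and mask topology
#' checks.
#'
#' @param arr Binary 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 `6` = offs[ord == 1, , drop = FALSE],
                 `18` = offs[ord >= 1 & ord <= 2, , drop = FALSE],
                 `26` = offs[ord >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26"))
  labels <- array(0L, d)
  fg <- which(arr > 0)
  next_label <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    while (length(queue) > 0) {
      idx <- arrayInd(queue, d)
      queue <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nb <- idx + matrix(offs[k, ], nrow(idx), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
        lin <- lin[arr[lin] > 0 & labels[lin] == 0L]
        if (length(lin) > 0) {
          labels[lin] <- next_label
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

#' Cohort summary statistics
#'
#' Per-case tumor voxel fraction, tumor long axis (mm, the maximal
#' point-to-point extent of the mask measured on surface voxels) and
#' laterality, plus their cohort means.
#'
#' @param cases Non-empty list of `phantom_case` objects.
#' @return List with a per-case `data.frame` (`case`, `fraction`,
#'   `long_axis_mm`, `n_components`, `bilateral`) and the cohort means
#'   `mean_fraction`, `bilateral_share`, `mean_long_axis_mm`.
#' @export
cohort_stats <- function(cases) {
  if (length(cases) == 0) stop("empty case list")
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    m <- cs$mask$data
    sp <- cs$mask$spacing
    labels <- label_components(m, 26L)
    ncomp <- max(labels)
    long_axis <- 0
    for (lab in seq_len(ncomp)) {
      comp <- array(as.numeric(labels == lab), dim = dim(m))
      pts <- surface_voxels(ct_mask(comp, sp))
      long_axis <- max(long_axis, point_set_diameter(pts))
    }
    data.frame(case = i, fraction = mean(m), long_axis_mm = long_axis,
               n_components = ncomp, bilateral = ncomp >= 2)
  })
  per_case <- do.call(rbind, rows)
  list(per_case = per_case,
       mean_fraction = mean(per_case$fraction),
       bilateral_share = mean(per_case$bilateral),
       mean_long_axis_mm = mean(per_case$long_axis_mm))
}

# Maximal pairwise distance within a point set (chunked).
point_set_diameter <- function(pts) {
  n <- nrow(pts)
  if (n == 0) return(0)
  if (n == 1) return(0)
  sq <- rowSums(pts^2)
  best <- 0
  step <- 512L
  for (i0 in seq(1L, n, by = step)) {
    i1 <- min(i0 + step - 1L, n)
    cross <- sq[i0:i1] + rep(sq, each = i1 - i0 + 1L) -
      2 * tcrossprod(pts[i0:i1, , drop = FALSE], pts)
    best <- max(best, max(cross))
  }
  sqrt(max(best, 0))
}

#' Write a cohort to disk
#'
#' Writes `case_####.nii.gz` / `case_####_mask.nii.gz` pairs plus a
#' `manifest.csv` (case id, laterality, tumor fraction, long axis mm, seed).
#'
#' @param cases List of `phantom_case` objects.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- cohort_stats(cases)
  manifest <- data.frame(
    case_id = sprintf("case_%04d", seq_along(cases)),
    laterality = ifelse(st$per_case$bilateral, "bilateral", "single"),
    tumor_fraction = st$per_case$fraction,
    long_axis_mm = st$per_case$long_axis_mm,
    seed = vapply(cases, function(cs) cs$spec$seed, integer(1)))
  for (i in seq_along(cases)) {
    write_volume(cases[[i]]$image, file.path(dir, sprintf("case_%04d.nii.gz", i)),
                 datatype = "float32")
    write_mask(cases[[i]]$mask, file.path(dir, sprintf("case_%04d_mask.nii.gz", i)))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
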