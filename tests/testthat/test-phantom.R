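# Synthetic phantom generator: determinism, geometry, cohort statistics.

test_that("phantom generation is deterministic and leaves the caller's RNG alone", {
  spec <- phantom_spec(grid_size = c(48L, 48L, 24L), spacing = c(1, 1, 1.5),
                       tumor_axes_mm = c(7, 5, 6), seed = 123)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  a <- make_phantom(spec)
  after <- runif(1)
  b <- make_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(before, after)   # caller RNG restored
})

test_that("mask topology matches n_tumors under 26-connectivity", {
  uni <- make_phantom(phantom_spec(grid_size = c(48L, 48L, 24L), spacing = c(1, 1, 1.5),
                                   n_tumors = 1L, tumor_axes_mm = c(7, 5, 6), seed = 5))
  expect_identical(max(label_components(uni$mask$data, 26L)), 1L)
  bi <- make_phantom(phantom_spec(grid_size = c(64L, 64L, 32L), spacing = c(1, 1, 1.5),
                                  n_tumors = 2L,
                                  tumor_axes_mm = rbind(c(6, 5, 5), c(6, 5, 5)),
                                  seed = 6))
  expect_identical(max(label_components(bi$mask$data, 26L)), 2L)
  expect_identical(dim(bi$image$data), dim(bi$mask$data))
})

test_that("degenerate noise settings give a piecewise-constant image with exact tumor HU", {
  spec <- phantom_spec(grid_size = c(40L, 40L, 24L), spacing = c(1, 1, 1.5),
                       noise_sd = 0, tumor_hu_sd = 0, edge_blur_sigma_mm = 0,
                       tumor_axes_mm = c(6, 5, 5), seed = 11)
  ph <- make_phantom(spec)
  vals <- sort(unique(as.vector(ph$image$data)))
  expect_lte(length(vals), 3)    # background, tumor, organ
  expect_true(all(ph$image$data[ph$mask$data > 0] == spec$tumor_hu_mean))
})

test_that("invalid specifications are rejected", {
  expect_error(phantom_spec(tumor_axes_mm = c(4, 3, 3)), "10 mm")
  expect_error(phantom_spec(n_tumors = 3L), "1 or 2")
  expect_error(phantom_spec(grid_size = c(0, 10, 10)), "positive")
  # a tumor that cannot fit inside a small grid
  expect_error(phantom_spec(grid_size = c(16L, 16L, 10L), spacing = c(1, 1, 1),
                            tumor_axes_mm = c(30, 30, 30), seed = 1),
               "outside the image grid")
})

test_that("mask voxel count tracks the analytic ellipsoid volume within 15%", {
  for (axes in list(c(8, 6, 7), c(10, 5, 6))) {
    spec <- phantom_spec(grid_size = c(64L, 64L, 40L), spacing = c(1, 1, 1),
                         tumor_axes_mm = axes, seed = 3)
    ph <- make_phantom(spec)
    analytic <- 4 / 3 * pi * prod(axes)    # mm^3; voxel volume is 1
    expect_lt(abs(sum(ph$mask$data) - analytic) / analytic, 0.15)
  }
})

test_that("cohort_stats reports fractions, laterality and long axes", {
  # hand-built case: 10^3 grid with 4 foreground voxels -> fraction 0.004
  m <- array(0, c(10, 10, 10))
  m[5, 5, 5] <- m[5, 6, 5] <- m[6, 5, 5] <- m[6, 6, 5] <- 1
  hand <- list(image = ct_volume(array(0, c(10, 10, 10)), c(1, 1, 1)),
               mask = ct_mask(m, c(1, 1, 1)))
  st <- cohort_stats(list(hand))
  expect_equal(st$per_case$fraction, 0.004)
  expect_identical(st$per_case$n_components, 1L)

  # analytic ellipsoid: long axis within one voxel diagonal of 2*max(semi-axes)
  spec <- phantom_spec(grid_size = c(64L, 64L, 40L), spacing = c(1, 1, 1),
                       tumor_axes_mm = c(9, 6, 6), seed = 21)
  st2 <- cohort_stats(list(make_phantom(spec)))
  expect_lt(abs(st2$per_case$long_axis_mm - 18), sqrt(3))

  # all-unilateral cohort -> 0% bilateral
  cases <- lapply(1:3, function(i) {
    make_phantom(phantom_spec(grid_size = c(48L, 48L, 24L), spacing = c(1, 1, 1.5),
                              tumor_axes_mm = c(6, 5, 5), seed = i))
  })
  expect_equal(cohort_stats(cases)$bilateral_share, 0)
  expect_error(cohort_stats(list()), "empty")
})

test_that("make_cohort honours contracts on a small draw", {
  expect_error(make_cohort(0), "at least 1")
  expect_error(make_cohort(5, bilateral_fraction = 1.2), "bilateral_fraction")
  expect_error(make_cohort(5, volume_fraction_target = 0.2), "volume_fraction_target")
  one <- make_cohort(1, seed = 77, grid_wh = 64L, d_range = c(24L, 32L))
  expect_length(one, 1)
  expect_s3_class(one[[1]], "phantom_case")
  expect_gte(max(label_components(one[[1]]$mask$data)), 1)
  # reproducible case streams
  again <- make_cohort(1, seed = 77, grid_wh = 64L, d_range = c(24L, 32L))
  expect_identical(one[[1]]$image$data, again[[1]]$image$data)
})

test_that("label_components distinguishes connectivities", {
  a <- array(0, c(4, 4, 1))
  a[1, 1, 1] <- 1
  a[2, 2, 1] <- 1   # diagonal neighbour: one component at 26, two at 6
  expect_identical(max(label_components(a, 26L)), 1L)
  expect_identical(max(label_components(a, 6L)), 2L)
  expect_error(label_components(a, 10L), "connectivity")
})

test_that("write_cohort emits NIfTI pairs and a manifest", {
  dir <- tempfile()
  cases <- make_cohort(2, seed = 5, grid_wh = 64L, d_range = c(20L, 24L))
  write_cohort(cases, dir)
  expect_true(file.exists(file.path(dir, "case_0001.nii.gz")))
  expect_true(file.exists(file.path(dir, "case_0002_mask.nii.gz")))
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(manifest), 2L)
  expect_true(all(c("case_id", "laterality", "tumor_fraction", "long_axis_mm", "seed")
                  %in% names(manifest)))
  expect_true(all(manifest$long_axis_mm >= 10 - sqrt(3)))
  back <- read_mask(file.path(dir, "case_0001_mask.nii.gz"))
  expect_equal(back$data, cases[[1]]$mask$data)
})
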