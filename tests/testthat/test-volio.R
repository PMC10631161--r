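# NIfTI I/O and the CT preprocessing chain.

test_that("NIfTI round-trip preserves values and spacing", {
  set.seed(1)
  a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_nifti(a, c(0.7, 0.7, 1.5), path, datatype = "float64")
    nii <- read_nifti(path)
    expect_identical(dim(nii$data), dim(a))
    expect_equal(nii$data, a)
    # pixdim is stored as float32 in the header
    expect_equal(nii$spacing, c(0.7, 0.7, 1.5), tolerance = 1e-6)
  }
})

test_that("mask round-trip through uint8 is exact and volume wrappers attach classes", {
  set.seed(2)
  m <- ct_mask(array(rbinom(6 * 6 * 6, 1, 0.3), c(6, 6, 6)), c(1, 1, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_s3_class(m2, "ct_mask")
  expect_equal(m2$data, m$data)
  expect_equal(m2$spacing, m$spacing)

  v <- ct_volume(array(runif(8 * 8 * 8, -100, 200), c(8, 8, 8)), c(1, 1, 1))
  pv <- tempfile(fileext = ".nii")
  write_volume(v, pv)
  v2 <- read_volume(pv)
  expect_s3_class(v2, "ct_volume")
  expect_equal(v2$data, v$data)
})

test_that("non-3D and non-NIfTI inputs are rejected with clear errors", {
  # hand-build a 4D header by patching dim[0] and dim[4]
  a <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  path <- tempfile(fileext = ".nii")
  write_nifti(a, c(1, 1, 1), path)
  raw <- readBin(path, "raw", file.size(path))
  raw[41:42] <- writeBin(4L, raw(), size = 2, endian = "little")   # dim[0] = 4
  raw[49:50] <- writeBin(3L, raw(), size = 2, endian = "little")   # dim[4] = 3
  p4 <- tempfile(fileext = ".nii")
  writeBin(raw, p4)
  expect_error(read_nifti(p4), "expected 3D volume")

  junk <- tempfile(fileext = ".nii")
  writeBin(as.raw(rep(7L, 500)), junk)
  expect_error(read_nifti(junk), "not a NIfTI-1 file")
})

test_that("windowing clips to [level - width/2, level + width/2] and is idempotent", {
  v <- ct_volume(array(c(300, -200, 40, 190, -110, 0), c(1, 2, 3)), c(1, 1, 1))
  w <- apply_window(v)
  expect_equal(as.vector(w$data), c(190, -110, 40, 190, -110, 0))
  expect_equal(apply_window(w)$data, w$data)
  expect_error(apply_window(v, width = 0), "width")
  # custom window
  w2 <- apply_window(v, level = 0, width = 100)
  expect_equal(range(w2$data), c(-50, 50))
})

test_that("normalization maps the window bounds to {0, 1} monotonically", {
  v <- ct_volume(array(c(-110, 40, 190, 65), c(1, 2, 2)), c(1, 1, 1))
  n <- normalize_volume(v)
  expect_equal(as.vector(n$data), c(0, 0.5, 1, 0.583333333), tolerance = 1e-9)
  expect_identical(n$domain, "normalized")
  # re-normalizing a normalized volume is rejected
  expect_error(normalize_volume(n), "already normalized")
  expect_error(apply_window(n), "HU-domain")
  # monotone on random windowed data
  set.seed(3)
  x <- sort(runif(50, -110, 190))
  nv <- normalize_volume(ct_volume(array(x, c(50, 1, 1)), c(1, 1, 1)))
  expect_true(all(diff(as.vector(nv$data)) >= 0))
})

test_that("resampling grid arithmetic follows the stated conventions", {
  out <- resampled_dims(c(512, 512, 101), c(0.7, 0.7, 1.5))
  expect_identical(out$dims, c(256L, 256L, 151L))
  expect_equal(out$spacing, c(1.4, 1.4, 1.0))
  # identity: factor 1 at target spacing
  out2 <- resampled_dims(c(64, 64, 33), c(1, 1, 1), inplane_factor = 1, target_z_spacing = 1)
  expect_identical(out2$dims, c(64L, 64L, 33L))
})

test_that("identity resample returns values unchanged; cubic is exact on linear ramps", {
  set.seed(4)
  v <- ct_volume(array(runif(16 * 16 * 10), c(16, 16, 10)), c(1, 1, 1))
  r <- resample_volume(v, inplane_factor = 1, target_z_spacing = 1)
  expect_equal(r$data, v$data, tolerance = 1e-6)
  # cubic interpolation reproduces a linear ramp exactly (interior)
  ramp <- ct_volume(array(rep(1:20, each = 16 * 16), c(16, 16, 20)), c(1, 1, 2))
  rz <- resample_volume(ramp, inplane_factor = 1, target_z_spacing = 1)
  expect_identical(dim(rz$data)[3], 39L)
  # interior points only: edge-clamped taps bend the ramp at the border
  expect_equal(rz$data[8, 8, 3:37], seq(2, 19, by = 0.5), tolerance = 1e-9)
})

test_that("mask resampling stays binary and small outputs are refused", {
  set.seed(5)
  m <- ct_mask(array(rbinom(24 * 24 * 12, 1, 0.4), c(24, 24, 12)), c(1, 1, 2))
  r <- resample_volume(m, inplane_factor = 0.5, target_z_spacing = 1)
  expect_true(all(r$data %in% c(0, 1)))
  expect_s3_class(r, "ct_mask")
  expect_identical(dim(r$data), c(12L, 12L, 23L))
  expect_error(resample_volume(m, inplane_factor = 0.25), "below 8")
})

test_that("preprocess composes window -> resample -> normalize; masks resample only", {
  spec <- phantom_spec(grid_size = c(32L, 32L, 20L), spacing = c(1, 1, 1.5),
                       tumor_axes_mm = c(6, 5, 5), seed = 9)
  ph <- make_phantom(spec)
  pp <- preprocess_case(ph, inplane_factor = 0.5)
  expect_identical(pp$image$domain, "normalized")
  expect_true(min(pp$image$data) >= 0 && max(pp$image$data) <= 1)
  expect_equal(pp$image$spacing, c(2, 2, 1))
  expect_identical(dim(pp$image$data), dim(pp$mask$data))
  expect_true(all(pp$mask$data %in% c(0, 1)))
})
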