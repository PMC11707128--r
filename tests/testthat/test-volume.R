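test_that("NIfTI round-trip preserves data, spacing and origin", {
  v <- image_volume(array(rnorm(8 * 7 * 6, -500, 400), c(8, 7, 6)),
                    spacing = c(0.8, 0.8, 1.5), origin = c(10, -5, 2.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data, tolerance = 1e-7)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)

  # constant air volume round-trips exactly
  a <- image_volume(array(-1000, c(5, 5, 5)), c(1, 1, 1))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(a, f2)
  expect_true(all(read_volume(f2)$data == -1000))
})

test_that("mask files are strict binary on disk", {
  m <- binary_mask(array(c(TRUE, FALSE), c(4, 4, 4)), c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  m2 <- read_mask(f)
  expect_identical(m2$data, m$data)
  v <- image_volume(array(0.5, c(3, 3, 3)), c(1, 1, 1))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(v, f2)
  expect_error(read_mask(f2), "other than")
})

test_that("constructors enforce geometry invariants", {
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, 0, 1)), "positive")
  expect_error(image_volume(array(0, c(4, 4)), c(1, 1, 1)))
  expect_error(binary_mask(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "strictly")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("intensity normalization clips and maps the window to [0, 1]", {
  v <- image_volume(array(c(-1024, 3071, 1023.5, -2000, 5000, 0),
                          c(6, 1, 1)), c(1, 1, 1))
  n <- normalize_intensities(v)
  expect_equal(as.numeric(n$data),
               c(0, 1, 0.5, 0, 1, 1024 / 4095))
  expect_error(normalize_intensities(v, c(100, 100)), "lo < hi")
  # custom window endpoints and midpoint
  n2 <- normalize_intensities(image_volume(array(c(-100, 300, 100), c(3, 1, 1)),
                                           c(1, 1, 1)), c(-100, 300))
  expect_equal(as.numeric(n2$data), c(0, 1, 0.5))
})

test_that("resampling hits the target shape with exact spacing arithmetic", {
  v <- image_volume(array(rnorm(32 * 32 * 28), c(32, 32, 28)),
                    spacing = c(0.8, 0.8, 1.0))
  r <- resample_to_shape(v, c(16, 16, 14))
  expect_identical(dim(r$data), c(16L, 16L, 14L))
  expect_equal(r$spacing, c(0.8 * 32 / 16, 0.8 * 32 / 16, 1.0 * 28 / 14))
  # physical extent preserved exactly under the cell-centred convention
  expect_equal(physical_extent(r), physical_extent(v))
  # the stage-1 arithmetic: 512 x 512 x 300 at (0.8, 0.8, 1.0)
  # to 160 x 160 x 224 gives spacing (2.56, 2.56, 300/224)
  v2 <- image_volume(array(0, c(512L, 512L, 300L)), c(0.8, 0.8, 1.0))
  sp <- v2$spacing * dim(v2$data) / c(160, 160, 224)
  expect_equal(sp, c(2.56, 2.56, 300 / 224))
})

test_that("resampling a constant volume stays constant; ramps stay linear", {
  v <- image_volume(array(7.5, c(20, 16, 16)), c(1, 1, 1))
  r <- resample_to_shape(v, c(10, 8, 8))
  expect_true(all(abs(r$data - 7.5) < 1e-12))
  # linear ramp along x, downsampled by 2: values match the analytic line
  # at the new voxel centres
  ramp <- image_volume(array(rep(0:31, 16 * 16), c(32, 16, 16)), c(1, 1, 1))
  r2 <- resample_to_shape(ramp, c(16, 16, 16))
  centres <- r2$origin[1] + (0:15) * r2$spacing[1]
  expect_equal(r2$data[, 1, 1], centres, tolerance = 1e-6)
})

test_that("nearest-mode resampling of a mask is binary; linear re-thresholds", {
  m <- binary_mask(voxel_ball(24, 8), c(1, 1, 1))
  up <- resample_to_shape(m, c(36, 36, 36))
  expect_type(up$data, "logical")
  dn <- resample_to_shape(m, c(12, 12, 12), mode = "linear")
  expect_type(dn$data, "logical")
  expect_gt(sum(dn$data), 0)
})

test_that("cropping shifts the origin and round-trips by re-embedding", {
  v <- image_volume(array(rnorm(10 * 10 * 10), c(10, 10, 10)),
                    spacing = c(1, 1, 1), origin = c(0, 0, 0))
  # identity crop
  full <- crop_to_box(v, rbind(c(1, 1, 1), c(10, 10, 10)))
  expect_equal(full$data, v$data)
  expect_equal(full$origin, v$origin)
  # origin arithmetic: 0-based start index 10 with unit spacing -> origin 10
  v2 <- image_volume(array(rnorm(12^3), c(12, 12, 12)), c(1, 1, 1))
  cr <- crop_to_box(v2, rbind(c(11, 1, 1), c(12, 12, 12)))
  expect_equal(cr$origin, c(10, 0, 0))
  # crop then re-embed reproduces the original values inside the box
  box <- rbind(c(3, 2, 4), c(8, 9, 7))
  cr2 <- crop_to_box(v, box)
  emb <- array(0, dim = dim(v$data))
  emb[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]] <- cr2$data
  expect_equal(emb[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]],
               v$data[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]])
  expect_error(crop_to_box(v, rbind(c(0, 1, 1), c(10, 10, 10))), "bounds")
})
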