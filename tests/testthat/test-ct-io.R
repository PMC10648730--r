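test_that("DICOM series round trip preserves voxels and all three spacings", {
  ph <- tiny_phantom()
  vol <- ct_volume(ph$volume$voxels, pixel_spacing = c(0.7, 0.7),
                   slice_positions = (seq_len(dim(ph$volume$voxels)[3]) - 1))
  dir <- withr::local_tempdir()
  write_volume(vol, dir, "dicom_series")
  expect_length(list.files(dir, pattern = "\\.dcm$"),
                dim(vol$voxels)[3])
  back <- read_series(dir)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$pixel_spacing_x, vol$pixel_spacing_x)
  expect_equal(back$pixel_spacing_y, vol$pixel_spacing_y)
  expect_equal(back$slice_positions, vol$slice_positions)
})

test_that("DICOM reading is independent of on-disk file order", {
  ph <- tiny_phantom()
  dir <- withr::local_tempdir()
  write_volume(ph$volume, dir, "dicom_series")
  files <- list.files(dir, full.names = TRUE)
  set.seed(1)
  shuffled <- sample(files)
  for (i in seq_along(files)) {
    file.rename(shuffled[i], paste0(shuffled[i], ".tmp"))
  }
  for (i in seq_along(files)) {
    file.rename(paste0(shuffled[i], ".tmp"),
                file.path(dir, sprintf("renamed_%03d.dcm", i)))
  }
  back <- read_series(dir)
  expect_identical(back$voxels, ph$volume$voxels)
  expect_equal(back$slice_positions, ph$volume$slice_positions)
})

test_that("NIfTI round trip preserves voxels and spacings", {
  ph <- tiny_phantom(noise_sigma = 10)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f, "nifti")
  back <- read_series(f)
  expect_equal(as.vector(back$voxels), as.vector(ph$volume$voxels))
  expect_equal(back$pixel_spacing_x[1], ph$volume$pixel_spacing_x[1])
  expect_equal(back$pixel_spacing_y[1], ph$volume$pixel_spacing_y[1])
  expect_equal(diff(back$slice_positions)[1],
               diff(ph$volume$slice_positions)[1])
})

test_that("series of clinical length (750+ slices) read back correctly", {
  set.seed(4)
  vox <- array(round(rnorm(16 * 16 * 750, 0, 20)), c(16, 16, 750))
  vol <- ct_volume(vox, pixel_spacing = c(0.7, 0.7), slice_spacing = 1)
  dir <- withr::local_tempdir()
  write_volume(vol, dir, "dicom_series")
  expect_length(list.files(dir, pattern = "\\.dcm$"), 750)
  back <- read_series(dir)
  expect_identical(back$voxels, vox)
  expect_true(all(diff(back$slice_positions) > 0))
})

test_that("unsupported format tokens and malformed volumes are rejected", {
  ph <- tiny_phantom()
  expect_error(write_volume(ph$volume, tempfile(), "analyze"))
  expect_error(ct_volume(ph$volume$voxels, pixel_spacing = c(0.7, 0.7),
                         slice_positions = rev(ph$volume$slice_positions)),
               "strictly increasing")
})

test_that("a single-slice series needs an explicit spacing tag", {
  vol1 <- ct_volume(array(round(rnorm(16 * 16, 0, 10)), c(16, 16, 1)),
                    pixel_spacing = c(1, 1), slice_positions = 0,
                    slice_spacing = 2.5)
  dir <- withr::local_tempdir()
  write_volume(vol1, dir, "dicom_series")
  back <- read_series(dir)
  expect_equal(back$slice_spacing, 2.5)
  expect_equal(slice_z_spacing(back), 2.5)
})

test_that("mixed matrix sizes in one directory are an error", {
  dir <- withr::local_tempdir()
  v1 <- ct_volume(array(0, c(16, 16, 2)), pixel_spacing = c(1, 1),
                  slice_spacing = 1)
  write_volume(v1, dir, "dicom_series")
  v2 <- ct_volume(array(0, c(32, 32, 1)), pixel_spacing = c(1, 1),
                  slice_positions = 10, slice_spacing = 1)
  write_dicom_slice_for_test <- renalvol:::write_dicom_slice
  write_dicom_slice_for_test(file.path(dir, "odd.dcm"), v2$voxels[, , 1],
                             1, 1, 10, 3, 1, "1.2.3", "1.2.3.4")
  expect_error(read_series(dir), "mixed matrix sizes")
})

test_that("non-uniform slice gaps warn but per-gap distances are kept", {
  vox <- array(round(rnorm(16 * 16 * 4, 0, 5)), c(16, 16, 4))
  vol <- ct_volume(vox, pixel_spacing = c(1, 1),
                   slice_positions = c(0, 1, 2, 4))
  dir <- withr::local_tempdir()
  write_volume(vol, dir, "dicom_series")
  expect_warning(back <- read_series(dir), "non-uniform")
  expect_equal(back$slice_positions, c(0, 1, 2, 4))
  expect_equal(slice_z_spacing(back), c(1, 1, 2, 2))
})

test_that("mask round trips are exact and grayscale inputs binarize on nonzero", {
  dir <- withr::local_tempdir()
  m0 <- matrix(0L, 32, 32)
  write_mask(m0, file.path(dir, "zero.png"))
  expect_identical(read_mask(file.path(dir, "zero.png")), m0)

  set.seed(2)
  m <- matrix(0L, 32, 32)
  m[sample(length(m), 200)] <- 1L
  write_mask(m, file.path(dir, "m.png"))
  expect_identical(read_mask(file.path(dir, "m.png")), m)
  expect_equal(sum(read_mask(file.path(dir, "m.png"))), 200)
  write_mask(m, file.path(dir, "m.nii"))
  expect_identical(read_mask(file.path(dir, "m.nii")), m)

  # grayscale values {0, 7, 255} -> foreground wherever nonzero
  g <- matrix(0, 16, 16)
  g[1:5, 1] <- 7 / 255
  g[6:16, 2] <- 1
  png::writePNG(g, file.path(dir, "gray.png"))
  got <- read_mask(file.path(dir, "gray.png"))
  expect_equal(sum(got), 5 + 11)
  expect_true(all(got %in% c(0L, 1L)))
})

test_that("non-2D mask input is an error", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 2))), f)
  expect_error(read_mask(f), "2D")
})
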