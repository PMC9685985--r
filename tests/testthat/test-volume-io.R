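# Volume containers, file formats, calibration and resampling.

test_that("container validation enforces the grid and calibration invariants", {
  expect_error(calibrated_volume(matrix(0, 2, 2)), "3D array")
  expect_error(calibrated_volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(calibrated_volume(array(2000, c(2, 2, 2)), calibrated = TRUE),
               "\\[0, 1064\\]")
  expect_error(binary_mask(array(2, c(2, 2, 2))), "0 or 1")
  m <- binary_mask(array(TRUE, c(2, 2, 2)))
  expect_identical(sort(unique(as.vector(m$voxels))), 1L)
})

test_that("write/read round-trips are exact for every supported format", {
  set.seed(42)
  td <- withr::local_tempdir()
  vi <- calibrated_volume(array(sample(0:2000, 64, replace = TRUE), c(4, 4, 4)),
                          spacing = c(0.7, 0.7, 0.7), origin = c(1, 2, 3))
  # integer-pixel formats: bit-identical voxels
  p <- file.path(td, "v.tif")
  write_volume(vi, p)
  vt <- read_volume(p, spacing = c(0.7, 0.7, 0.7))
  expect_identical(vt$voxels, vi$voxels)
  pd <- file.path(td, "dcm")
  write_volume(vi, pd, format = "dicom_series")
  vd <- read_volume(pd)
  expect_identical(vd$voxels, vi$voxels)
  expect_equal(vd$spacing, vi$spacing)
  expect_equal(vd$origin, vi$origin)
  expect_false(vd$calibrated)
  # MetaImage: lossless for arbitrary doubles, carries calibration flag
  vf <- rescale_grayscale(vi, air_value = 0, bone_value = 2000)
  for (ext in c("mha", "mhd")) {
    pm <- file.path(td, paste0("v.", ext))
    write_volume(vf, pm)
    vm <- read_volume(pm)
    expect_identical(vm$voxels, vf$voxels)
    expect_equal(vm$spacing, vf$spacing)
    expect_true(vm$calibrated)
  }
  # masks round-trip as 8-bit MetaImage
  m <- binary_mask(array(sample(0:1, 64, replace = TRUE), c(4, 4, 4)))
  pm <- file.path(td, "m.mha")
  write_volume(m, pm)
  m2 <- read_volume(pm)
  expect_equal(m2$voxels, m$voxels + 0)
})

test_that("a TIFF stack of 3 slices of 2x2 yields a 2x2x3 grid", {
  td <- withr::local_tempdir()
  v <- calibrated_volume(array(0:11 + 0, c(2, 2, 3)))
  p <- file.path(td, "s.tif")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_identical(dim(v2$voxels), c(2L, 2L, 3L))
  expect_identical(v2$voxels, v$voxels)
})

test_that("DICOM slices with conflicting pixel spacing raise a format error", {
  td <- withr::local_tempdir()
  d1 <- file.path(td, "a"); d2 <- file.path(td, "b")
  write_volume(calibrated_volume(array(0, c(4, 4, 1)), spacing = c(1, 1, 1)),
               d1, format = "dicom_series")
  write_volume(calibrated_volume(array(0, c(4, 4, 1)), spacing = c(0.5, 0.5, 1)),
               d2, format = "dicom_series")
  file.copy(file.path(d2, "slice0001.dcm"), file.path(d1, "slice0002.dcm"))
  expect_error(read_volume(d1), "conflicting PixelSpacing")
})

test_that("the calibration map fixes the endpoints, midpoint and clipping", {
  v <- calibrated_volume(array(c(100, 500, 900, 1200, 0, 100, 900, 900),
                               c(2, 2, 2)))
  r <- rescale_grayscale(v, air_value = 100, bone_value = 900)
  expect_true(r$calibrated)
  expect_equal(r$voxels[1, 1, 1], 0)      # air endpoint
  expect_equal(r$voxels[1, 2, 1], 1064)   # bone endpoint
  expect_equal(r$voxels[2, 1, 1], 532)    # midpoint, linear
  expect_equal(r$voxels[2, 2, 1], 1064)   # above bone: clipped
  expect_equal(r$voxels[1, 1, 2], 0)      # below air: clipped
  expect_error(rescale_grayscale(v, 900, 100), "greater")
  # idempotent on an already-calibrated volume with identity references
  expect_equal(rescale_grayscale(r, 0, 1064)$voxels, r$voxels)
})

test_that("downsampling is block-mean pooling with partial-block averaging", {
  set.seed(7)
  a <- array(runif(8^3, 0, 1064), c(8, 8, 8))
  v <- calibrated_volume(a, spacing = c(0.5, 0.5, 0.5))
  expect_identical(downsample(v, 1), v)
  # brute-force per-block mean oracle
  d <- downsample(v, 2)
  oracle <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    oracle[i, j, k] <- mean(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                              (2 * k - 1):(2 * k)])
  expect_equal(d$voxels, oracle)
  expect_equal(d$spacing, c(1, 1, 1))
  # constant volumes stay constant; partial blocks average available voxels
  cst <- downsample(calibrated_volume(array(7, c(5, 5, 5))), 2)
  expect_true(all(cst$voxels == 7))
  expect_identical(dim(cst$voxels), c(3L, 3L, 3L))
  expect_error(downsample(v, 0), "positive")
})

test_that("downsample by a*b equals downsample by a then b on divisible dims", {
  set.seed(8)
  v <- calibrated_volume(array(runif(12^3), c(12, 12, 12)))
  expect_equal(downsample(v, 6)$voxels, downsample(downsample(v, 2), 3)$voxels)
  expect_equal(working_resolution_factor(
    calibrated_volume(array(0, c(4, 4, 1030)))), 3L)
})

test_that("midplanes are the central index slices", {
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  mp <- extract_midplanes(calibrated_volume(a))
  # floor(5/2) = 2 in 0-based indexing -> R index 3: the bright voxel shows
  # up in all three planes
  expect_equal(mp$axial[3, 3], 1)
  expect_equal(mp$coronal[3, 3], 1)
  expect_equal(mp$sagittal[3, 3], 1)
  # degenerate axis: the single slice is the midplane
  v1 <- calibrated_volume(array(seq_len(16) + 0, c(1, 4, 4)))
  expect_equal(extract_midplanes(v1)$sagittal, v1$voxels[1, , ])
})
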