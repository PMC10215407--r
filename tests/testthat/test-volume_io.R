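test_that("voxel_volume validates its geometry", {
  expect_error(voxel_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D array")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  v <- voxel_volume(array(0, c(4, 3, 2)), c(1, 2, 3))
  expect_identical(v$num, c(4L, 3L, 2L))
})

test_that("DICOM series round-trips grid, counts, spacing and origin", {
  set.seed(10)
  vol <- voxel_volume(array(sample(0:4000, 6 * 7 * 5, TRUE), c(6, 7, 5)),
                      spacing = c(0.5, 2.0, 0.5), origin = c(-3, 1, 2.5))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- load_dicom_series(dir)
  expect_identical(back$num, vol$num)
  expect_equal(back$intensities, vol$intensities + 0, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("single-slice series loads with stacking count 1", {
  vol <- voxel_volume(array(7L, c(3, 1, 4)), spacing = c(1, 1.5, 1))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- load_dicom_series(dir)
  expect_identical(back$num[2], 1L)
  expect_equal(back$intensities, vol$intensities + 0)
})

test_that("series loading sorts slices by spatial position", {
  set.seed(11)
  vol <- voxel_volume(array(sample(0:99, 4 * 6 * 4, TRUE), c(4, 6, 4)),
                      spacing = c(1, 1.25, 1))
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(vol, dir)
  # shuffle file names so directory order disagrees with position
  tmp <- file.path(dir, "zz_renamed.dcm")
  file.rename(paths[1], tmp)
  back <- load_dicom_series(dir)
  expect_equal(back$intensities, vol$intensities + 0)
})

test_that("load_dicom_series reports empty and malformed series", {
  dir <- withr::local_tempdir()
  expect_error(load_dicom_series(dir), "no series")
  write_dicom_series(voxel_volume(array(1L, c(2, 2, 2)), c(1, 1, 1)),
                     dir)
  write_dicom_series(voxel_volume(array(1L, c(3, 1, 3)), c(1, 1, 1)),
                     file.path(dir, "other"))
  file.copy(file.path(dir, "other", "slice_0001.dcm"),
            file.path(dir, "slice_9999.dcm"))
  expect_error(load_dicom_series(dir), "malformed series")
})

test_that("written series is readable by an independent DICOM parser", {
  vol <- voxel_volume(array(0:119, c(4, 5, 6)), spacing = c(0.5, 2, 0.5))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  script <- paste(
    "import pydicom, sys, glob",
    sprintf("fs = sorted(glob.glob('%s/*.dcm'))", dir),
    "ds = pydicom.dcmread(fs[1])",
    "print(ds.Rows, ds.Columns, int(ds.InstanceNumber))",
    "print(float(ds.PixelSpacing[0]), float(ds.PixelSpacing[1]))",
    "print(int(ds.pixel_array[-1, 0]))",  # lower-left pixel of slice 2
    sep = "\n")
  out <- system2("python", "-", input = script, stdout = TRUE)
  expect_equal(out[1], "6 4 2")
  expect_equal(out[2], "0.5 0.5")
  # lower-left of slice j=2 is voxel (1, 2, 1): value 0-based = 4
  expect_equal(out[3], "4")
})

test_that("extract_slice returns the exact grid plane per axis", {
  set.seed(12)
  vol <- voxel_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)), c(1, 1, 1))
  sl <- extract_slice(vol, "y", 1)
  expect_equal(sl$pixels, vol$intensities[, 1, ])
  expect_identical(c(sl$width, sl$height), c(5L, 7L))
  # random axis/index vs brute-force loop copy
  for (axis in c("x", "y", "z")) {
    a <- match(axis, c("x", "y", "z"))
    k <- sample(dim(vol$intensities)[a], 1)
    sl <- extract_slice(vol, axis, k)
    oracle <- switch(axis,
      x = {o <- matrix(0, 6, 7)
           for (j in 1:6) for (l in 1:7) o[j, l] <- vol$intensities[k, j, l]
           o},
      y = {o <- matrix(0, 5, 7)
           for (i in 1:5) for (l in 1:7) o[i, l] <- vol$intensities[i, k, l]
           o},
      z = {o <- matrix(0, 5, 6)
           for (i in 1:5) for (j in 1:6) o[i, j] <- vol$intensities[i, j, k]
           o})
    expect_equal(unname(sl$pixels), oracle)
  }
  expect_error(extract_slice(vol, "y", 0), "slice out of range")
  expect_error(extract_slice(vol, "y", 7), "slice out of range")
})

test_that("extracting all slices and restacking rebuilds the volume", {
  set.seed(13)
  vol <- voxel_volume(array(rnorm(4 * 5 * 3), c(4, 5, 3)), c(1, 2, 1),
                      origin = c(1, 1, 1))
  for (axis in c("x", "y", "z")) {
    n <- vol$num[match(axis, c("x", "y", "z"))]
    slices <- lapply(seq_len(n), function(k) extract_slice(vol, axis, k))
    back <- stack_slices(slices, axis, vol$spacing, vol$origin)
    expect_equal(back$intensities, vol$intensities)
  }
})

test_that("normalize_volume maps to [0,1], zeros constants, idempotent", {
  const <- voxel_volume(array(7, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(normalize_volume(const)$intensities == 0))
  v255 <- voxel_volume(array(c(0, 255, sample(0:255, 25, TRUE)), c(3, 3, 3)),
                       c(1, 1, 1))
  expect_equal(normalize_volume(v255)$intensities,
               v255$intensities / 255)
  set.seed(14)
  rnd <- voxel_volume(array(rnorm(60), c(4, 5, 3)), c(1, 1, 1))
  n1 <- normalize_volume(rnd)
  expect_equal(range(n1$intensities), c(0, 1))
  expect_equal(normalize_volume(n1)$intensities, n1$intensities)
  expect_equal(n1$spacing, rnd$spacing)
})

test_that("crop_volume tightens the grid to the occupied box", {
  vol <- voxel_volume(array(0, c(8, 8, 8)), c(1, 2, 1))
  vol$intensities[3:5, 2:7, 4:6] <- 10
  cr <- crop_volume(vol)
  expect_identical(cr$num, c(3L, 6L, 3L))
  expect_equal(cr$origin, c(2, 2, 3))
  expect_error(crop_volume(voxel_volume(array(0, c(2, 2, 2)), c(1, 1, 1))),
               "empty occupancy")
})
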