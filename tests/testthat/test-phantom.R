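test_that("phantom generation is deterministic given the seed", {
  a <- generate_head_phantom(phantom_spec(seed = 9))
  b <- generate_head_phantom(phantom_spec(seed = 9))
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth$ventricle_mask, b$truth$ventricle_mask)
  c <- generate_head_phantom(phantom_spec(seed = 10))
  expect_false(identical(a$volume$intensities, c$volume$intensities))
})

test_that("a centered spherical ventricle yields a centered truth centroid", {
  center <- c(32, 36, 32)
  ph <- generate_head_phantom(phantom_spec(
    ventricles = list(list(center = center, semiaxes = c(8, 8, 8))),
    seed = 1))
  expect_true(all(abs(ph$truth$centroid_mm - center) <=
                    ph$volume$spacing / 2))
})

test_that("largest-component truth picks the bigger of two blobs", {
  center <- c(32, 36, 32)
  ph <- generate_head_phantom(phantom_spec(
    ventricles = list(
      list(center = center + c(-12, 0, -10), semiaxes = c(2.4, 2.4, 2.4)),
      list(center = center + c(9, 0, 8), semiaxes = c(6, 6, 6))),
    seed = 2))
  sizes <- ph$truth$component_sizes
  expect_length(sizes, 2)
  expect_gt(sizes[2], sizes[1])
  # exhaustive voxel count from the mask itself
  expect_identical(sum(ph$truth$ventricle_mask), sum(sizes))
  # truth centroid comes from the larger blob
  big <- which(ph$truth$ventricle_mask == 1, arr.ind = TRUE)
  in_big <- sqrt(rowSums(sweep(
    sweep(big, 2, 0.5) * rep(ph$volume$spacing, each = nrow(big)),
    2, center + c(9, 0, 8))^2)) < 7
  expect_true(all(abs(ph$truth$centroid_voxel - colMeans(big[in_big, ])) < 1))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(ventricles = list(
    list(center = c(32, 36, 32), semiaxes = c(40, 8, 8)))), "invalid spec")
  expect_error(phantom_spec(ventricles = list(
    list(center = c(5, 5, 5), semiaxes = c(4, 4, 4)))), "invalid spec")
  expect_error(phantom_spec(ventricles = list(
    list(center = c(32, 36, 32), semiaxes = c(-1, 2, 2)))), "invalid spec")
  # overlapping blobs cannot represent two distinct components
  expect_error(phantom_spec(ventricles = list(
    list(center = c(30, 36, 32), semiaxes = c(5, 5, 5)),
    list(center = c(34, 36, 32), semiaxes = c(5, 5, 5)))),
    "separated")
})

test_that("scalp mesh is closed and spans exactly the ellipsoid box", {
  mesh <- ellipsoid_mesh(c(10, 20, 30), c(5, 6, 7), subdivisions = 2)
  edges <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
                 mesh$faces[, c(3, 1)])
  keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(keys) == 2))  # every edge shared by two triangles
  lo <- apply(mesh$vertices, 2, min); hi <- apply(mesh$vertices, 2, max)
  expect_equal(lo, c(10, 20, 30) - c(5, 6, 7), tolerance = 1e-9)
  expect_equal(hi, c(10, 20, 30) + c(5, 6, 7), tolerance = 1e-9)
})

test_that("head-mask voxel centres lie inside the scalp surface", {
  ph <- generate_head_phantom(phantom_spec(seed = 4))
  idx <- which(ph$truth$head_mask == 1, arr.ind = TRUE)
  pts <- sweep(idx, 2, 0.5) * rep(ph$volume$spacing, each = nrow(idx))
  spec <- ph$spec
  q <- rowSums(sweep(sweep(pts, 2, spec$scalp_center), 2,
                     spec$scalp_semiaxes, "/")^2)
  expect_true(all(q < 1))
})

test_that("mesh OFF files round-trip", {
  mesh <- ellipsoid_mesh(c(0, 0, 0), c(2, 3, 4), subdivisions = 1)
  path <- withr::local_tempfile(fileext = ".off")
  write_mesh_off(mesh, path)
  back <- read_mesh_off(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  expect_identical(back$faces, mesh$faces)
})

test_that("tracking stream honors jitter, duration and determinism", {
  still <- generate_tracking_stream(c(1, 2, 3), jitter_sd = 0,
                                    n_samples = 10, seed = 1)
  expect_true(all(still$x == 1 & still$y == 2 & still$z == 3))
  minute <- generate_tracking_stream(c(0, 0, 0), n_samples = 60,
                                     interval_s = 1, seed = 1)
  expect_equal(max(minute$t) - min(minute$t), 59)
  big <- generate_tracking_stream(c(5, 5, 5), jitter_sd = 0.05,
                                  n_samples = 10000, seed = 2)
  for (axis in c("x", "y", "z")) {
    expect_lt(abs(sd(big[[axis]]) - 0.05) / 0.05, 0.05)
  }
  expect_identical(
    generate_tracking_stream(c(5, 5, 5), 0.05, 100, 1, seed = 3),
    generate_tracking_stream(c(5, 5, 5), 0.05, 100, 1, seed = 3))
})

test_that("pose streams round-trip through CSV", {
  s <- generate_tracking_stream(c(1, 1, 1), 0.1, 20, 0.5, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_stream(s, path)
  back <- read_pose_stream(path)
  expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-12)
})

test_that("slice dataset is grouped, binary and normalized", {
  data <- phantom_slice_dataset(n_groups = 3, slices_per_group = 6, seed = 5)
  expect_identical(dim(data$images), c(64L, 64L, 18L))
  expect_identical(sort(unique(data$groups)), 1:3)
  expect_true(all(data$masks %in% c(0, 1)))
  expect_gte(min(data$images), 0)
  expect_lte(max(data$images), 1)
  # most slices contain ventricle, all contain head tissue
  pos <- apply(data$masks, 3, sum)
  expect_gte(mean(pos > 0), 0.7)
})
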