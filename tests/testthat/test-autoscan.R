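cube_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  f <- rbind(c(1, 2, 4), c(1, 4, 3), c(5, 8, 6), c(5, 7, 8),
             c(1, 6, 2), c(1, 5, 6), c(3, 4, 8), c(3, 8, 7),
             c(1, 3, 7), c(1, 7, 5), c(2, 8, 4), c(2, 6, 8))
  structure(list(vertices = v, faces = f), class = "scalp_mesh")
}

test_that("scanning a unit cube finds its faces exactly", {
  rp <- scan_reference_points(cube_mesh(), sweep_step_mm = 0.05)
  expect_equal(rp$RP_x_L, 0, tolerance = 0.05)
  expect_equal(rp$RP_x_R, 1, tolerance = 0.05)
  expect_equal(rp$RP_y_min, 0, tolerance = 0.05)
  expect_equal(rp$RP_z_max, 1, tolerance = 0.05)
})

test_that("scanning a sphere mesh finds center +/- radius per axis", {
  mesh <- ellipsoid_mesh(c(10, 20, 15), c(5, 5, 5), subdivisions = 3)
  rp <- scan_reference_points(mesh, sweep_step_mm = 0.1)
  expect_equal(rp$RP_x_L, 5, tolerance = 0.15)
  expect_equal(rp$RP_x_R, 15, tolerance = 0.15)
  expect_equal(rp$RP_y_min, 15, tolerance = 0.15)
  expect_equal(rp$RP_y_max, 25, tolerance = 0.15)
  expect_equal(rp$RP_z_min, 10, tolerance = 0.15)
  expect_equal(rp$RP_z_max, 20, tolerance = 0.15)
})

test_that("voxel-blob scanning matches the brute-force occupied extremes", {
  for (seed in 1:10) {
    dims <- c(12, 10, 14)
    m <- random_blob_mask(seed, dims)
    spacing <- c(0.8, 1.4, 0.9)
    occ <- voxel_occupancy(m, spacing = spacing, origin = c(2, -1, 0))
    step <- 0.1
    rp <- scan_reference_points(occ, sweep_step_mm = step)
    idx <- which(m != 0, arr.ind = TRUE)
    centers <- sweep(idx, 2, 0.5) * rep(spacing, each = nrow(idx))
    centers <- sweep(centers, 2, c(2, -1, 0), `+`)
    lo <- apply(centers, 2, min); hi <- apply(centers, 2, max)
    got_lo <- c(rp$RP_x_L, rp$RP_y_min, rp$RP_z_min)
    got_hi <- c(rp$RP_x_R, rp$RP_y_max, rp$RP_z_max)
    expect_true(all(abs(got_lo - lo) <= step + 1e-12))
    expect_true(all(abs(got_hi - hi) <= step + 1e-12))
  }
})

test_that("mesh and voxel scans agree on a convex phantom", {
  ph <- generate_head_phantom(phantom_spec(seed = 6))
  occ <- voxel_occupancy(ph$truth$head_mask, spacing = ph$volume$spacing)
  rp_vox <- scan_reference_points(occ, sweep_step_mm = 0.1)
  rp_mesh <- scan_reference_points(ph$truth$scalp_mesh, sweep_step_mm = 0.1)
  tol <- max(0.1, max(ph$volume$spacing))
  for (nm in c("RP_x_L", "RP_x_R", "RP_y_min", "RP_y_max",
               "RP_z_min", "RP_z_max")) {
    expect_lt(abs(rp_vox[[nm]] - rp_mesh[[nm]]), tol)
  }
})

test_that("shrinking the sweep step tightens the reference-point bound", {
  mesh <- ellipsoid_mesh(c(0, 0, 0), c(4, 4, 4), subdivisions = 3)
  steps <- c(1, 0.25, 0.02)
  err <- sapply(steps, function(step) {
    rp <- scan_reference_points(mesh, sweep_step_mm = step)
    r_true <- max(mesh$vertices[, 1])
    abs(rp$RP_x_L + r_true)
  })
  # each sweep lands within its own step of the true extreme, so the
  # guaranteed bound tightens monotonically with the step size
  expect_true(all(err <= steps + 1e-9))
})

test_that("empty objects cannot be scanned", {
  expect_error(
    scan_reference_points(voxel_occupancy(array(0L, c(3, 3, 3)))),
    "nothing to scan")
})

test_that("derive_extents computes Dis and T per the thickness formulas", {
  pts <- list(RP_x_L = 0, RP_x_R = 180, RP_y_min = 0, RP_y_max = 120,
              RP_z_min = 10, RP_z_max = 160)
  frame <- derive_extents(pts, c(180L, 60L, 100L))
  expect_equal(frame$Dis, c(180, 120, 150))
  expect_equal(frame$T, c(1.0, 2.0, 1.5))
  expect_error(derive_extents(list(RP_x_L = 5, RP_x_R = 5, RP_y_min = 0,
                                   RP_y_max = 1, RP_z_min = 0, RP_z_max = 1),
                              c(2L, 2L, 2L)),
               "degenerate object")
})

test_that("scanned phantom thickness recovers the generator spacing", {
  ph <- generate_head_phantom(phantom_spec(seed = 7))
  occ <- voxel_occupancy(ph$truth$head_mask, spacing = ph$volume$spacing)
  rp <- scan_reference_points(occ, sweep_step_mm = 0.1)
  head_vol <- crop_volume(ph$volume, mask = ph$truth$head_mask)
  frame <- derive_extents(rp, head_vol)
  expect_equal(frame$T, ph$volume$spacing, tolerance = 0.1)
})

test_that("point_to_slice_indices floors, clamps and validates", {
  frame <- derive_extents(
    list(RP_x_L = 10, RP_x_R = 60, RP_y_min = 0, RP_y_max = 80,
         RP_z_min = -5, RP_z_max = 45),
    c(50L, 40L, 25L))  # T = 1, 2, 2
  at_min <- point_to_slice_indices(c(10, 0, -5), frame)
  expect_identical(c(at_min$TrueX, at_min$TrueY, at_min$TrueZ),
                   c(1L, 1L, 1L))
  expect_equal(at_min$raw, c(0, 0, 0))
  mid <- point_to_slice_indices(c(10 + 2.5 * 1, 0, -5), frame)
  expect_identical(mid$TrueX, 3L)
  expect_equal(mid$raw[1], 2.5)
  top <- point_to_slice_indices(c(60, 80, 45), frame)
  expect_identical(c(top$TrueX, top$TrueY, top$TrueZ), c(50L, 40L, 25L))
  expect_error(point_to_slice_indices(c(9.99, 0, 0), frame),
               "outside scanned object")
})

test_that("random in-frame points match an interval-membership oracle", {
  set.seed(20)
  frame <- derive_extents(
    list(RP_x_L = -7, RP_x_R = 23, RP_y_min = 2, RP_y_max = 47,
         RP_z_min = 0, RP_z_max = 33),
    c(13L, 18L, 11L))
  mins <- frame$min
  for (i in 1:200) {
    p <- mins + runif(3) * frame$Dis
    got <- point_to_slice_indices(p, frame)
    oracle <- sapply(1:3, function(a) {
      # linear scan over slice boundary intervals
      bounds <- mins[a] + (0:frame$Num[a]) * frame$T[a]
      k <- max(which(p[a] >= bounds - 1e-12)) # interval containing p
      min(k, frame$Num[a])
    })
    expect_identical(c(got$TrueX, got$TrueY, got$TrueZ),
                     as.integer(oracle))
  }
})

test_that("slice index is monotone and slice centers map to themselves", {
  frame <- derive_extents(
    list(RP_x_L = 0, RP_x_R = 30, RP_y_min = 0, RP_y_max = 60,
         RP_z_min = 0, RP_z_max = 20),
    c(15L, 24L, 10L))
  xs <- seq(0, 30, by = 0.37)
  idx <- sapply(xs, function(x)
    point_to_slice_indices(c(x, 1, 1), frame)$TrueX)
  expect_true(all(diff(idx) >= 0))
  for (a in 1:3) {
    for (k in seq_len(frame$Num[a])) {
      p <- frame$min
      p[a] <- frame$min[a] + (k - 0.5) * frame$T[a]
      got <- point_to_slice_indices(p, frame)
      expect_identical(c(got$TrueX, got$TrueY, got$TrueZ)[a], as.integer(k))
    }
  }
})

test_that("reference frames round-trip through JSON", {
  pts <- list(RP_x_L = 1.5, RP_x_R = 58, RP_y_min = 2, RP_y_max = 70,
              RP_z_min = 0.5, RP_z_max = 61)
  frame <- derive_extents(pts, c(56L, 45L, 60L))
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_frame(frame, path)
  back <- read_reference_frame(path)
  expect_equal(back$min, frame$min)
  expect_equal(back$T, frame$T)
  expect_identical(back$Num, frame$Num)
})
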