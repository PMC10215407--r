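# Synthetic head phantoms: ellipsoidal scalp/skull shells around brain
# tissue with ventricle blobs of known geometry, plus simulated tracked-pose
# streams. Every downstream stage is testable against the returned ground
# truth.

#' Specify a synthetic head phantom
#'
#' The phantom is a stack of concentric ellipsoids: a scalp surface, a 2 mm
#' skin layer, a skull shell of `skull_thickness_mm`, brain tissue inside,
#' and one or more ellipsoidal ventricle (CSF) blobs. Tissue intensities
#' are specified in Hounsfield units; Gaussian detector noise is added in
#' HU and the result is then brain-windowed (default level 40, width 80 HU)
#' onto an 8-bit display scale, the representation a clinical
#' ventricle-segmentation pipeline consumes. Air and bone clip flat to
#' 0/255 as on a real windowed CT; integer stored values survive 16-bit
#' DICOM round trips exactly.
#'
#' @param grid_shape integer length-3 voxel counts `(Num_x, Num_y, Num_z)`.
#' @param spacing voxel spacing in mm (anisotropic allowed).
#' @param scalp_center,scalp_semiaxes scalp ellipsoid, mm in head space.
#' @param skull_thickness_mm skull shell thickness.
#' @param ventricles list of `list(center=, semiaxes=)` blobs, mm; each must
#'   lie strictly inside the scalp.
#' @param intensities named vector with entries `background`, `scalp`,
#'   `skull`, `brain`, `ventricle`, in Hounsfield units.
#' @param window CT display window `c(level, width)` in HU applied after
#'   noise; stored values are `[0, 255]`.
#' @param noise_sd Gaussian detector-noise standard deviation (HU).
#' @param seed integer; fixes all randomness of the generator.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 48L, 64L),
                         spacing = c(1.0, 1.5, 1.0),
                         scalp_center = grid_shape * spacing / 2,
                         scalp_semiaxes = c(29, 33, 29),
                         skull_thickness_mm = 4,
                         ventricles = list(
                           list(center = scalp_center + c(4, 2, 3),
                                semiaxes = c(9, 11, 8))),
                         intensities = c(background = -1000, scalp = 60,
                                         skull = 800, brain = 35,
                                         ventricle = 5),
                         window = c(level = 40, width = 80),
                         noise_sd = 5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            all(scalp_semiaxes > 0), skull_thickness_mm >= 0,
            noise_sd >= 0, length(ventricles) >= 1L)
  required <- c("background", "scalp", "skull", "brain", "ventricle")
  if (!all(required %in% names(intensities))) {
    stop("intensities must name: ", paste(required, collapse = ", "))
  }
  for (v in ventricles) {
    if (any(v$semiaxes <= 0)) stop("invalid spec: ventricle semi-axes must be > 0")
    # conservative containment: blob bounding box inside scalp ellipsoid box
    if (any(abs(v$center - scalp_center) + v$semiaxes >= scalp_semiaxes)) {
      stop("invalid spec: ventricle blob not strictly inside the scalp")
    }
  }
  if (length(ventricles) > 1L) {
    margin <- 2 * max(spacing)  # keeps blob voxel sets non-adjacent
    for (a in seq_len(length(ventricles) - 1L)) {
      for (b in (a + 1L):length(ventricles)) {
        va <- ventricles[[a]]; vb <- ventricles[[b]]
        sep <- abs(va$center - vb$center) > va$semiaxes + vb$semiaxes + margin
        if (!any(sep)) {
          stop("invalid spec: ventricle blobs must be mutually separated")
        }
      }
    }
  }
  structure(
    list(grid_shape = grid_shape, spacing = as.numeric(spacing),
         scalp_center = as.numeric(scalp_center),
         scalp_semiaxes = as.numeric(scalp_semiaxes),
         skull_thickness_mm = skull_thickness_mm,
         ventricles = ventricles,
         intensities = intensities, window = as.numeric(window),
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

inside_ellipsoid <- function(px, py, pz, center, semiaxes) {
  ((px - center[1]) / semiaxes[1])^2 +
    ((py - center[2]) / semiaxes[2])^2 +
    ((pz - center[3]) / semiaxes[3])^2 < 1
}

#' Generate a synthetic head phantom with ground truth
#'
#' Deterministic given `spec$seed`. The ventricle mask is exactly the set of
#' voxel centres inside the ventricle blobs; the truth records the centroid
#' (mm and voxel) of the largest blob, its stacking-axis slice index, and a
#' closed triangulated scalp surface.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `head_phantom` with elements `volume`
#'   ([voxel_volume()]), `truth` (fields `ventricle_mask`, `head_mask`,
#'   `centroid_mm`, `centroid_voxel`, `slice_index`, `component_sizes`,
#'   `scalp_mesh`) and `spec`.
#' @examples
#' ph <- generate_head_phantom(phantom_spec(seed = 7))
#' ph$truth$centroid_mm
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape; sp <- spec$spacing
  cx <- (seq_len(n[1]) - 0.5) * sp[1]
  cy <- (seq_len(n[2]) - 0.5) * sp[2]
  cz <- (seq_len(n[3]) - 0.5) * sp[3]
  px <- array(rep(cx, times = n[2] * n[3]), n)
  py <- array(rep(rep(cy, each = n[1]), times = n[3]), n)
  pz <- array(rep(cz, each = n[1] * n[2]), n)

  skin_mm <- 2
  head <- inside_ellipsoid(px, py, pz, spec$scalp_center, spec$scalp_semiaxes)
  skull_outer <- inside_ellipsoid(px, py, pz, spec$scalp_center,
                                  pmax(spec$scalp_semiaxes - skin_mm, 1e-6))
  brain <- inside_ellipsoid(
    px, py, pz, spec$scalp_center,
    pmax(spec$scalp_semiaxes - skin_mm - spec$skull_thickness_mm, 1e-6))

  ints <- spec$intensities
  vol <- array(ints[["background"]], n)
  vol[head] <- ints[["scalp"]]
  vol[skull_outer] <- ints[["skull"]]
  vol[brain] <- ints[["brain"]]

  mask <- array(FALSE, n)
  sizes <- integer(length(spec$ventricles))
  blob_centroids_mm <- matrix(0, length(spec$ventricles), 3)
  blob_centroids_vox <- matrix(0, length(spec$ventricles), 3)
  for (b in seq_along(spec$ventricles)) {
    vb <- spec$ventricles[[b]]
    inb <- inside_ellipsoid(px, py, pz, vb$center, vb$semiaxes)
    sizes[b] <- sum(inb)
    if (sizes[b] > 0L) {
      idx <- which(inb, arr.ind = TRUE)
      blob_centroids_vox[b, ] <- colMeans(idx)
      blob_centroids_mm[b, ] <- c(mean(px[inb]), mean(py[inb]), mean(pz[inb]))
    }
    mask <- mask | inb
  }
  vol[mask] <- ints[["ventricle"]]

  if (spec$noise_sd > 0) {
    vol <- with_seed(spec$seed, vol + rnorm(length(vol), sd = spec$noise_sd))
  }
  # brain windowing: HU -> 8-bit display scale, clipping outside the window
  w_lo <- spec$window[1] - spec$window[2] / 2
  vol <- round(pmin(pmax((vol - w_lo) / spec$window[2], 0), 1) * 255)

  if (all(sizes == 0L)) stop("invalid spec: ventricles contain no voxels")
  largest <- which.max(sizes)  # ties -> smallest index
  centroid_mm <- blob_centroids_mm[largest, ]
  truth <- list(
    ventricle_mask = array(as.integer(mask), n),
    head_mask = array(as.integer(head), n),
    centroid_mm = centroid_mm,
    centroid_voxel = blob_centroids_vox[largest, ],
    slice_index = min(max(floor(centroid_mm[2] / sp[2]) + 1, 1), n[2]),
    component_sizes = sizes,
    scalp_mesh = ellipsoid_mesh(spec$scalp_center, spec$scalp_semiaxes)
  )
  structure(
    list(volume = voxel_volume(vol, spacing = sp), truth = truth, spec = spec),
    class = "head_phantom"
  )
}

# ---- scalp surface mesh -----------------------------------------------------

#' Triangulated ellipsoid surface
#'
#' Closed manifold mesh built by recursive octahedron subdivision projected
#' onto the unit sphere, then scaled by the semi-axes. Every edge is shared
#' by exactly two triangles.
#'
#' @param center,semiaxes ellipsoid geometry (mm).
#' @param subdivisions octahedron subdivision depth (3 gives 512 faces).
#' @return A `scalp_mesh`: list with `vertices` (V x 3) and `faces` (F x 3,
#'   1-based).
#' @export
ellipsoid_mesh <- function(center, semiaxes, subdivisions = 3L) {
  verts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  faces <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                 c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(verts)
    new_verts <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ])
      m <- m / sqrt(sum(m^2))
      new_verts[[length(new_verts) + 1L]] <<- m
      id <- nv + length(new_verts)
      edge_mid[[key]] <- id
      id
    }
    new_faces <- matrix(0L, nrow(faces) * 4L, 3L)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1]; b <- faces[f, 2]; c <- faces[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      new_faces[(f - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    verts <- rbind(verts, do.call(rbind, new_verts))
    faces <- new_faces
  }
  verts <- sweep(sweep(verts, 2, semiaxes, `*`), 2, center, `+`)
  storage.mode(faces) <- "integer"
  structure(list(vertices = verts, faces = faces), class = "scalp_mesh")
}

#' Write / read a mesh in OFF format
#'
#' @param mesh a `scalp_mesh`.
#' @param path text `.off` file.
#' @return `write_mesh_off` invisibly returns `path`; `read_mesh_off`
#'   returns a `scalp_mesh`.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$faces, 1, function(f)
    sprintf("3 %d %d %d", f[1] - 1L, f[2] - 1L, f[3] - 1L)), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  face_rows <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    scan(text = l, quiet = TRUE))
  faces <- t(vapply(face_rows, function(r) as.integer(r[2:4]) + 1L,
                    integer(3)))
  structure(list(vertices = verts, faces = faces), class = "scalp_mesh")
}

#' Build a grouped, labeled slice dataset from phantom "patients"
#'
#' Emulates the clinical training database: each group is one synthetic
#' patient (a phantom with its own ventricle position and size), from which
#' stacking-axis slices are taken together with the ground-truth ventricle
#' masks. Slices intersecting the ventricle are preferred; a fraction of
#' ventricle-free slices is kept so the network also sees negatives.
#' Negatives are drawn from slices that still contain head anatomy, as in
#' a clinical head series where every slice shows tissue. Intensities are
#' min-max normalized per patient volume.
#'
#' @param n_groups number of phantom patients.
#' @param slices_per_group slices sampled per patient.
#' @param grid_shape phantom grid; y-slices are `grid_shape[1] x
#'   grid_shape[3]` pixels.
#' @param seed integer; fixes phantom geometry and slice sampling.
#' @param negative_fraction fraction of slices drawn from ventricle-free
#'   planes.
#' @return A [labeled_slice_set()] with group ids `1..n_groups`.
#' @export
phantom_slice_dataset <- function(n_groups = 10L, slices_per_group = 25L,
                                  grid_shape = c(64L, 48L, 64L),
                                  seed = 1L, negative_fraction = 0.2) {
  h <- grid_shape[1]; w <- grid_shape[3]
  n_total <- n_groups * slices_per_group
  images <- array(0, c(h, w, n_total))
  masks <- array(0, c(h, w, n_total))
  groups <- integer(n_total)
  k <- 0L
  for (g in seq_len(n_groups)) {
    geom <- with_seed(seed * 1000L + g, list(
      offset = runif(3, -6, 6),
      semi = c(runif(1, 6, 11), runif(1, 7, 13), runif(1, 5, 10))))
    center <- grid_shape * c(1.0, 1.5, 1.0) / 2
    spec <- phantom_spec(
      grid_shape = grid_shape,
      ventricles = list(list(center = center + geom$offset,
                             semiaxes = geom$semi)),
      seed = seed * 1000L + g)
    ph <- generate_head_phantom(spec)
    norm <- normalize_volume(ph$volume)
    has_vent <- which(apply(ph$truth$ventricle_mask, 2, sum) > 0)
    has_head <- which(apply(ph$truth$head_mask, 2, sum) > 100)
    no_vent <- setdiff(has_head, has_vent)
    n_neg <- min(round(slices_per_group * negative_fraction), length(no_vent))
    picks <- with_seed(seed * 1000L + g + 500L, c(
      sample(has_vent, slices_per_group - n_neg, replace =
               length(has_vent) < slices_per_group - n_neg),
      sample(no_vent, n_neg)))
    for (j in picks) {
      k <- k + 1L
      images[, , k] <- extract_slice(norm, "y", j)$pixels
      masks[, , k] <- ph$truth$ventricle_mask[, j, ]
      groups[k] <- g
    }
  }
  labeled_slice_set(images, masks, groups)
}

# ---- simulated tracking -----------------------------------------------------

#' Simulate a tracked-pose stream
#'
#' Emulates recording the centre position of a tracked marker (head-model
#' centre or scalpel tip) at fixed intervals: position = `center` plus
#' isotropic Gaussian jitter. The default jitter magnitude reproduces the
#' sub-0.1 mm stability regime of a well-anchored image-target tracker.
#'
#' @param center length-3 true marker position (mm).
#' @param jitter_sd per-axis Gaussian jitter SD (mm), >= 0.
#' @param n_samples number of samples (>= 2); default one per second for a
#'   minute.
#' @param interval_s sampling interval (s).
#' @param seed integer seed; fixes the jitter.
#' @return A `pose_stream` data.frame with columns `t`, `x`, `y`, `z`.
#' @export
generate_tracking_stream <- function(center, jitter_sd = 0.048,
                                     n_samples = 60L, interval_s = 1,
                                     seed = 1L) {
  stopifnot(length(center) == 3L, n_samples >= 2L, jitter_sd >= 0,
            interval_s > 0)
  jit <- with_seed(seed,
                   matrix(rnorm(3L * n_samples, sd = jitter_sd), ncol = 3L))
  out <- data.frame(
    t = (seq_len(n_samples) - 1L) * interval_s,
    x = center[1] + jit[, 1],
    y = center[2] + jit[, 2],
    z = center[3] + jit[, 3]
  )
  class(out) <- c("pose_stream", "data.frame")
  out
}

#' Write / read a pose stream as CSV
#'
#' @param stream a `pose_stream` (columns `t`, `x`, `y`, `z`).
#' @param path CSV path.
#' @return `write_pose_stream` invisibly returns `path`; `read_pose_stream`
#'   returns a `pose_stream`.
#' @export
write_pose_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream)[c("t", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_stream
#' @export
read_pose_stream <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "x", "y", "z") %in% names(df)))
  if (nrow(df) < 2L || any(diff(df$t) <= 0)) {
    stop("pose stream needs >= 2 samples with strictly increasing timestamps")
  }
  class(df) <- c("pose_stream", "data.frame")
  df
}
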