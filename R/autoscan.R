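# Virtual-object automatic scanning: axis-perpendicular planes sweep inward
# from each side of the object; the first plane position whose intersection
# with the object is non-empty is a reference point. Six reference points
# (two per axis) define the head's extent, from which per-axis DICOM slice
# thicknesses and the tracked-point -> slice-index mapping follow.

#' Voxel occupancy object for scanning
#'
#' Wraps a binary mask (or a thresholded [voxel_volume()]) as the set of
#' occupied voxel centres in head space.
#'
#' @param x a [voxel_volume()], or a logical/0-1 3D array.
#' @param threshold intensity cutoff when `x` is a volume.
#' @param spacing,origin geometry when `x` is a bare array.
#' @return A `voxel_occupancy` with fields `mask`, `spacing`, `origin`.
#' @export
voxel_occupancy <- function(x, threshold = 0, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  if (inherits(x, "voxel_volume")) {
    mask <- x$intensities > threshold
    spacing <- x$spacing
    origin <- x$origin
  } else if (is.array(x) && length(dim(x)) == 3L) {
    mask <- x != 0
  } else {
    stop("x must be a voxel_volume or a 3D array")
  }
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_occupancy")
}

# Per-axis interval representation used by the plane collision test:
# a list with `lo`/`hi` numeric vectors per axis (triangle spans for meshes,
# center +/- 0 for voxel point sets) plus the collision tolerance.
scan_geometry <- function(object, sweep_step_mm) {
  if (inherits(object, "scalp_mesh")) {
    v <- object$vertices
    if (nrow(v) == 0L) stop("nothing to scan: empty mesh")
    lapply(1:3, function(a) {
      tri <- matrix(v[t(object$faces), a], ncol = 3L, byrow = TRUE)
      list(lo = apply(tri, 1, min), hi = apply(tri, 1, max), tol = 0)
    })
  } else if (inherits(object, "voxel_occupancy")) {
    if (!any(object$mask)) stop("nothing to scan: empty occupancy")
    idx <- which(object$mask, arr.ind = TRUE)
    lapply(1:3, function(a) {
      coords <- object$origin[a] + (idx[, a] - 0.5) * object$spacing[a]
      coords <- sort(unique(coords))
      # a marching plane "collides" with a voxel centre it has stepped onto
      list(lo = coords, hi = coords, tol = sweep_step_mm / 2)
    })
  } else {
    stop("object must be a scalp_mesh or voxel_occupancy")
  }
}

plane_hits <- function(geom_axis, pos) {
  any(geom_axis$lo - geom_axis$tol <= pos & pos <= geom_axis$hi + geom_axis$tol)
}

sweep_axis <- function(geom_axis, from, step, direction) {
  pos <- from
  limit <- 10 * (max(geom_axis$hi) - min(geom_axis$lo)) / step + 100
  for (i in seq_len(ceiling(limit))) {
    if (plane_hits(geom_axis, pos)) return(pos)
    pos <- pos + direction * step
  }
  stop("sweep failed to collide with the object")  # unreachable for valid input
}

#' Scan an object for its six axis reference points
#'
#' For each axis a virtual plane perpendicular to that axis marches inward
#' from either side in steps of `sweep_step_mm`; the first position where
#' the plane intersects the object is recorded. For any object the result
#' equals the axis-aligned bounding extremes of the occupied set to within
#' one sweep step.
#'
#' @param object a `scalp_mesh` or [voxel_occupancy()].
#' @param sweep_step_mm plane marching step (mm), > 0.
#' @return A list with the six reference points `RP_x_L`, `RP_x_R`,
#'   `RP_y_min`, `RP_y_max`, `RP_z_min`, `RP_z_max` and `sweep_step_mm`.
#' @export
scan_reference_points <- function(object, sweep_step_mm = 0.1) {
  stopifnot(sweep_step_mm > 0)
  geom <- scan_geometry(object, sweep_step_mm)
  pts <- lapply(geom, function(g) {
    lo0 <- min(g$lo); hi0 <- max(g$hi)
    c(min = sweep_axis(g, lo0 - 2 * sweep_step_mm, sweep_step_mm, +1),
      max = sweep_axis(g, hi0 + 2 * sweep_step_mm, sweep_step_mm, -1))
  })
  list(RP_x_L = pts[[1]][["min"]], RP_x_R = pts[[1]][["max"]],
       RP_y_min = pts[[2]][["min"]], RP_y_max = pts[[2]][["max"]],
       RP_z_min = pts[[3]][["min"]], RP_z_max = pts[[3]][["max"]],
       sweep_step_mm = sweep_step_mm)
}

#' Derive per-axis extents and slice thicknesses
#'
#' From the six reference points, the per-axis extent is
#' `Dis_a = max_a - min_a` and the slice thickness `T_a = Dis_a / Num_a`,
#' with `Num_a` the DICOM slice count on that axis.
#'
#' @param points six reference points as returned by
#'   [scan_reference_points()].
#' @param volume the [voxel_volume()] supplying slice counts, or an integer
#'   vector `c(Num_x, Num_y, Num_z)`.
#' @return A `reference_frame`: reference points plus `Dis` (mm extents),
#'   `T` (mm thicknesses) and `Num` (slice counts), each length-3 (x, y, z).
#' @export
derive_extents <- function(points, volume) {
  num <- if (inherits(volume, "voxel_volume")) volume$num
         else as.integer(volume)
  stopifnot(length(num) == 3L, all(num >= 1L))
  mins <- c(points$RP_x_L, points$RP_y_min, points$RP_z_min)
  maxs <- c(points$RP_x_R, points$RP_y_max, points$RP_z_max)
  if (any(!is.finite(c(mins, maxs)))) stop("invalid reference points")
  dis <- maxs - mins
  if (any(dis <= 0)) stop("degenerate object: zero extent on an axis")
  structure(
    list(RP_x_L = points$RP_x_L, RP_x_R = points$RP_x_R,
         RP_y_min = points$RP_y_min, RP_y_max = points$RP_y_max,
         RP_z_min = points$RP_z_min, RP_z_max = points$RP_z_max,
         min = mins, max = maxs,
         Dis = dis, T = dis / num, Num = num),
    class = "reference_frame"
  )
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame>\n")
  for (a in 1:3) {
    cat(sprintf("  %s: [%.3f, %.3f] mm  Dis %.3f  T %.4f  Num %d\n",
                c("x", "y", "z")[a], x$min[a], x$max[a],
                x$Dis[a], x$T[a], x$Num[a]))
  }
  invisible(x)
}

#' Map a tracked 3D point to DICOM slice indices
#'
#' Computes the raw per-axis value `(Ep_a - min_a) / T_a` and the 1-based
#' integer slice index `floor(raw) + 1`, clamped to `[1, Num_a]`. A point
#' anywhere within the physical span of slice `k` maps to `k`. A component
#' below the axis minimum is a tracking fault and raises an error rather
#' than being clamped.
#'
#' @param ep length-3 tracked point (mm), e.g. the scalpel edge point.
#' @param frame a [derive_extents()] reference frame.
#' @return A `slice_indices` list: `TrueX`, `TrueY`, `TrueZ` (integers) and
#'   `raw` (length-3 fractional values).
#' @export
point_to_slice_indices <- function(ep, frame) {
  stopifnot(inherits(frame, "reference_frame"), length(ep) == 3L)
  ep <- as.numeric(ep)
  if (any(ep < frame$min - 1e-9)) {
    stop("outside scanned object: point below the axis minimum reference point")
  }
  raw <- (ep - frame$min) / frame$T
  idx <- pmin(pmax(floor(raw) + 1, 1), frame$Num)
  structure(list(TrueX = as.integer(idx[1]), TrueY = as.integer(idx[2]),
                 TrueZ = as.integer(idx[3]), raw = raw),
            class = "slice_indices")
}

#' Serialize / restore a reference frame as JSON
#'
#' @param frame a `reference_frame`.
#' @param path JSON path.
#' @return `write_reference_frame` invisibly returns `path`;
#'   `read_reference_frame` returns a `reference_frame`.
#' @export
write_reference_frame <- function(frame, path) {
  jsonlite::write_json(unclass(frame), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_frame
#' @export
read_reference_frame <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  derive_extents(x, as.integer(x$Num))
}
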