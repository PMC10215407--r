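# 2D slice pick <-> 3D head-space target conversion. Pixel coordinates have
# their origin at the lower-left of the displayed slice, matching the
# head-space origin at the lower left of the head; the y coordinate grows
# into the DICOM stack, and slice 1 anchors the origin plane (y = 0).

#' Describe a 2D target selection on a DICOM slice
#'
#' @param x,y pixel coordinates of the pick, lower-left origin;
#'   `0 <= x <= width`, `0 <= y <= height`.
#' @param slice 1-based stacking-axis slice number `N_target`.
#' @param width,height slice pixel dimensions (`I_dicomX2D`, `I_dicomY2D`).
#' @return A `target_selection_2d` list.
#' @export
target_selection_2d <- function(x, y, slice, width, height) {
  stopifnot(width >= 1, height >= 1, slice >= 1)
  if (x < 0 || x > width || y < 0 || y > height) {
    stop("selection out of bounds: pick outside the slice pixel extent")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 slice = as.integer(slice),
                 width = as.numeric(width), height = as.numeric(height)),
            class = "target_selection_2d")
}

#' Describe the physical extent of the head volume
#'
#' @param lengths length-3 physical head lengths along x, y, z
#'   (`I_X3D`, `I_Y3D`, `I_Z3D`), mm.
#' @param n_total total DICOM slice count on the stacking axis (`N_total`).
#' @return A `volume_extent` list.
#' @export
volume_extent <- function(lengths, n_total) {
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) == 3L, all(lengths > 0), n_total >= 1)
  structure(list(lengths = lengths, n_total = as.integer(n_total)),
            class = "volume_extent")
}

#' @rdname volume_extent
#' @param volume a [voxel_volume()] to summarize.
#' @export
volume_extent_of <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  volume_extent(volume$num * volume$spacing, volume$num[2])
}

#' Convert a 2D slice pick to a 3D head-space target
#'
#' The pick `(X_2D, Y_2D)` on slice `N_target` maps to
#' `(X_2D * I_X3D / I_dicomX2D,  (I_Y3D / N_total) * (N_target - 1),
#' Y_2D * I_Z3D / I_dicomY2D)`: pixel coordinates scale linearly onto the
#' head's physical extent and the slice number selects the y plane, with
#' slice 1 on the origin plane.
#'
#' @param sel a [target_selection_2d()].
#' @param ext a [volume_extent()].
#' @return A `target_3d`: list with `position` (length-3 mm).
#' @examples
#' sel <- target_selection_2d(128, 64, slice = 10, width = 256, height = 256)
#' target_2d_to_3d(sel, volume_extent(c(180, 150, 160), 100))$position
#' @export
target_2d_to_3d <- function(sel, ext) {
  stopifnot(inherits(sel, "target_selection_2d"),
            inherits(ext, "volume_extent"))
  if (sel$slice > ext$n_total) {
    stop("selection out of bounds: slice number exceeds N_total")
  }
  pos <- c(sel$x * ext$lengths[1] / sel$width,
           (ext$lengths[2] / ext$n_total) * (sel$slice - 1),
           sel$y * ext$lengths[3] / sel$height)
  structure(list(position = pos), class = "target_3d")
}

#' Convert a 3D head-space point back to a 2D slice selection
#'
#' Inverse of [target_2d_to_3d()] up to slice quantization on y: the slice
#' number is `floor(y * N_total / I_Y3D) + 1` (the nearest slice plane at or
#' below `y`), and pixel coordinates are scaled back exactly, snapping to
#' the integer pixel grid when within 1e-6 pixels.
#'
#' @param p a `target_3d` or length-3 numeric position (mm).
#' @param ext a [volume_extent()].
#' @param slice_dims length-2 pixel dimensions `c(width, height)` of the
#'   displayed slice.
#' @return A [target_selection_2d()].
#' @export
target_3d_to_2d <- function(p, ext, slice_dims) {
  if (inherits(p, "target_3d")) p <- p$position
  p <- as.numeric(p)
  stopifnot(length(p) == 3L, inherits(ext, "volume_extent"),
            length(slice_dims) == 2L)
  if (any(p < -1e-9) || any(p > ext$lengths + 1e-9)) {
    stop("outside head volume: position beyond the physical extent")
  }
  snap <- function(v) {
    r <- round(v)
    ifelse(abs(v - r) < 1e-6, r, v)
  }
  x2d <- snap(p[1] * slice_dims[1] / ext$lengths[1])
  y2d <- snap(p[3] * slice_dims[2] / ext$lengths[3])
  n <- floor(p[2] * ext$n_total / ext$lengths[2] + 1e-9) + 1
  n <- min(max(n, 1), ext$n_total)
  target_selection_2d(x2d, y2d, n, slice_dims[1], slice_dims[2])
}
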