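# Surgical target recommendation: connected components of the predicted
# ventricle mask, largest region, centre point, predicted stacking-axis
# plane.

#' Label connected components of a binary mask
#'
#' 3D labeling uses a 26-neighborhood by default (the 3D analogue of the
#' classic 8-connected 2D labeling); `mode = "slice"` labels each
#' stacking-axis slice independently with 8-connectivity.
#'
#' @param mask binary (0/1 or logical) array; a matrix is treated as a
#'   single-slice volume.
#' @param connectivity 6, 18 or 26 for `mode = "volume"`; 4 or 8 for
#'   `mode = "slice"`.
#' @param mode `"volume"` (default, one labeling across slices) or
#'   `"slice"` (independent per-slice labelings).
#' @return A `component_labeling`: `labels` (integer array, 0 background,
#'   component ids contiguous from 1), `counts` (voxels per id),
#'   `connectivity`, `mode`.
#' @export
label_components <- function(mask, connectivity = NULL,
                             mode = c("volume", "slice")) {
  mode <- match.arg(mode)
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("mask must be a 2D or 3D array")
  }
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("mask must be binary")
  }
  m <- array(as.integer(mask != 0), dim(mask))
  if (mode == "volume") {
    connectivity <- connectivity %||% 26L
    if (!connectivity %in% c(6L, 18L, 26L)) {
      stop("volume connectivity must be 6, 18 or 26")
    }
    res <- label_components_cpp(as.vector(m), dim(m), as.integer(connectivity))
    labels <- res$labels
    counts <- res$counts
  } else {
    connectivity <- connectivity %||% 8L
    if (!connectivity %in% c(4L, 8L)) {
      stop("slice connectivity must be 4 or 8")
    }
    conn3 <- if (connectivity == 4L) 6L else 26L
    labels <- array(0L, dim(m))
    counts <- numeric(0)
    offset <- 0L
    for (j in seq_len(dim(m)[2])) {
      sl <- array(m[, j, ], c(dim(m)[1], 1L, dim(m)[3]))
      res <- label_components_cpp(as.vector(sl), dim(sl), conn3)
      lab <- array(res$labels, c(dim(m)[1], dim(m)[3]))
      lab[lab > 0L] <- lab[lab > 0L] + offset
      labels[, j, ] <- lab
      counts <- c(counts, res$counts)
      offset <- offset + length(res$counts)
    }
  }
  structure(list(labels = labels, counts = counts,
                 connectivity = as.integer(connectivity), mode = mode),
            class = "component_labeling")
}

#' Largest connected component
#'
#' @param labeling a [label_components()] result.
#' @return The integer id of the component with the most voxels; ties go to
#'   the smallest id.
#' @export
largest_component <- function(labeling) {
  stopifnot(inherits(labeling, "component_labeling"))
  if (length(labeling$counts) == 0L) {
    stop("no ventricle detected: mask is empty")
  }
  which.max(labeling$counts) # ties -> smallest id
}

#' Recommend a surgical target from a mask volume
#'
#' Selects the largest connected ventricular region, takes the arithmetic
#' mean of its voxel coordinates as the centre point (rounded to the
#' nearest voxel, ties toward the lower index, so the target lies on a
#' displayable slice) and reports the stacking-axis slice index of that
#' voxel as the predicted axis plane.
#'
#' @param mask binary mask volume (array or [voxel_volume()] of 0/1).
#' @param frame a `reference_frame` from [derive_extents()] giving the mm
#'   geometry; `NULL` returns voxel coordinates only.
#' @param connectivity,mode passed to [label_components()].
#' @return A `recommended_target`: `voxel` (i, j, k), `centroid_voxel`
#'   (fractional), `mm` (head-space position, if `frame` given),
#'   `plane` (predicted stacking-axis slice index), `component_id`,
#'   `component_size`.
#' @export
recommend_target <- function(mask, frame = NULL, connectivity = NULL,
                             mode = c("volume", "slice")) {
  geom <- NULL
  if (inherits(mask, "voxel_volume")) {
    geom <- list(origin = mask$origin, spacing = mask$spacing)
    mask <- mask$intensities
  }
  labeling <- label_components(mask, connectivity, mode)
  id <- largest_component(labeling)
  idx <- which(labeling$labels == id, arr.ind = TRUE)
  centroid <- unname(colMeans(idx))
  voxel <- round_half_down(centroid)
  mm <- NULL
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "reference_frame"))
    mm <- frame$min + (voxel - 0.5) * frame$T
  } else if (!is.null(geom)) {
    mm <- geom$origin + (voxel - 0.5) * geom$spacing
  }
  structure(
    list(voxel = as.integer(voxel), centroid_voxel = centroid, mm = mm,
         plane = as.integer(voxel[2]), component_id = id,
         component_size = labeling$counts[id]),
    class = "recommended_target"
  )
}

# nearest integer, exact halves toward the lower index
round_half_down <- function(x) ceiling(x - 0.5)

#' @export
print.recommended_target <- function(x, ...) {
  cat(sprintf(
    "<recommended_target> voxel (%d, %d, %d), plane %d, component %d (%g voxels)\n",
    x$voxel[1], x$voxel[2], x$voxel[3], x$plane, x$component_id,
    x$component_size))
  if (!is.null(x$mm)) {
    cat(sprintf("  head space: (%.2f, %.2f, %.2f) mm\n",
                x$mm[1], x$mm[2], x$mm[3]))
  }
  invisible(x)
}

#' Serialize a recommended target as JSON
#'
#' @param target a `recommended_target`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_recommended_target <- function(target, path) {
  jsonlite::write_json(unclass(target), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
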