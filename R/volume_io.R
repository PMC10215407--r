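#' Construct a voxel volume
#'
#' A `voxel_volume` is the in-memory model of a DICOM series: a 3D intensity
#' grid with per-axis slice counts, physical voxel spacings (mm) and an
#' origin in head space. The grid is indexed `[i, j, k]` along the x
#' (left-right), y (stacking) and z (inferior-superior) axes; the voxel
#' `(i, j, k)` is centred at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param intensities numeric 3D array, dimensions `(Num_x, Num_y, Num_z)`.
#' @param spacing numeric length-3, mm per voxel step on x, y, z; all > 0.
#' @param origin numeric length-3, head-space position of the volume's
#'   lower-left corner (default the head origin `c(0, 0, 0)`).
#' @return An object of class `voxel_volume` with fields `intensities`,
#'   `num` (slice counts `Num_x`, `Num_y`, `Num_z`), `spacing`, `origin`.
#' @examples
#' vol <- voxel_volume(array(0, c(4, 3, 4)), spacing = c(1, 2, 1))
#' vol$num
#' @export
voxel_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("intensities must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be a finite 3D point")
  }
  structure(
    list(intensities = intensities,
         num = as.integer(dim(intensities)),
         spacing = spacing,
         origin = origin),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %.3g/%.3g/%.3g mm, origin (%g, %g, %g)\n",
    x$num[1], x$num[2], x$num[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

axis_index <- function(axis) {
  i <- match(match.arg(as.character(axis), c("x", "y", "z")), c("x", "y", "z"))
  i
}

#' Physical coordinates of voxel centres along one axis
#'
#' @param volume a [voxel_volume()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Numeric vector of mm positions, one per slice on that axis.
#' @export
voxel_centers <- function(volume, axis) {
  a <- axis_index(axis)
  volume$origin[a] + (seq_len(volume$num[a]) - 0.5) * volume$spacing[a]
}

# ---- DICOM series -----------------------------------------------------------

#' Write a voxel volume as a single-frame DICOM series
#'
#' One uncompressed explicit-VR little-endian CT file is written per slice
#' along the stacking (y) axis. Intensities must be integers in
#' `[0, 65535]` (stored 16-bit unsigned, as CT scanners store offset
#' Hounsfield values).
#'
#' @param volume a [voxel_volume()].
#' @param directory output directory, created if missing.
#' @return Invisibly, the vector of file paths written.
#' @seealso [load_dicom_series()]
#' @export
write_dicom_series <- function(volume, directory) {
  stopifnot(inherits(volume, "voxel_volume"))
  v <- volume$intensities
  if (max(abs(v - round(v))) > 1e-6) {
    stop("volume intensities must be integer-valued for DICOM output")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  sp <- volume$spacing
  nx <- volume$num[1]; ny <- volume$num[2]; nz <- volume$num[3]
  series_uid <- dicom_uid(paste0("1.", sample.int(1e6, 1L)))
  study_uid <- dicom_uid(paste0("2.", sample.int(1e6, 1L)))
  # rows run along -z (row 1 = superior), columns along +x
  orientation <- c(1, 0, 0, 0, 0, -1)
  paths <- character(ny)
  for (j in seq_len(ny)) {
    # [rows = z top-down, cols = x]
    pixels <- t(round(v[, j, ]))[nz:1, , drop = FALSE]
    position <- volume$origin +
      c(0.5 * sp[1], (j - 0.5) * sp[2], (nz - 0.5) * sp[3])
    paths[j] <- file.path(directory, sprintf("slice_%04d.dcm", j))
    write_dicom_file(paths[j], pixels,
                     instance_number = j,
                     position = position,
                     orientation = orientation,
                     pixel_spacing = c(sp[3], sp[1]),
                     slice_spacing = sp[2],
                     series_uid = series_uid,
                     study_uid = study_uid)
  }
  invisible(paths)
}

#' Read a single-frame DICOM series into a voxel volume
#'
#' Files are sorted by the projection of their image position onto the slice
#' normal (ascending head-space position along the stacking axis), with ties
#' broken by instance number. Pixel spacing and inter-slice spacing become
#' the voxel spacing.
#'
#' @param directory a directory holding `.dcm` files of one series.
#' @return A [voxel_volume()].
#' @export
load_dicom_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) {
    stop("no series: no DICOM files found in ", directory)
  }
  slices <- lapply(files, read_dicom_file)
  rows <- vapply(slices, `[[`, 0L, "rows")
  cols <- vapply(slices, `[[`, 0L, "cols")
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L) {
    stop("malformed series: inconsistent slice dimensions")
  }
  nz <- rows[1]; nx <- cols[1]; ny <- length(slices)
  orient <- slices[[1]]$orientation %||% c(1, 0, 0, 0, 0, -1)
  normal <- c(orient[2] * orient[6] - orient[3] * orient[5],
              orient[3] * orient[4] - orient[1] * orient[6],
              orient[1] * orient[5] - orient[2] * orient[4])
  proj <- vapply(slices, function(s) {
    p <- s$position %||% c(0, 0, s$instance %||% 0)
    sum(p * normal)
  }, 0)
  inst <- vapply(slices, function(s) s$instance %||% 0L, 0L)
  ord <- order(proj, inst)
  slices <- slices[ord]; proj <- proj[ord]
  ps <- slices[[1]]$pixel_spacing %||% c(1, 1)
  spacing_y <- if (ny > 1L) {
    d <- diff(proj)
    if (any(d <= 0)) stop("malformed series: duplicate slice positions")
    median(d)
  } else {
    (slices[[1]]$slice_spacing %||% 1)[1]
  }
  vol <- array(0, dim = c(nx, ny, nz))
  for (j in seq_len(ny)) {
    # invert writer layout: [rows = z top-down, cols = x]
    vol[, j, ] <- t(slices[[j]]$pixels[nz:1, , drop = FALSE])
  }
  spacing <- c(ps[2], spacing_y, ps[1])
  pos1 <- slices[[1]]$position %||% c(0, 0, 0)
  origin <- pos1 - c(0.5 * spacing[1], 0.5 * spacing[2], (nz - 0.5) * spacing[3])
  voxel_volume(vol, spacing = spacing, origin = origin)
}

# ---- slices -----------------------------------------------------------------

#' Extract an axis-perpendicular slice image
#'
#' Returns the plane of the intensity grid perpendicular to `axis` at the
#' 1-based `index`. The pixel matrix is indexed `[horizontal, vertical]`
#' from the lower-left of the displayed image: for a y-axis (stacking)
#' slice, width runs along x and height along z.
#'
#' @param volume a [voxel_volume()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param index 1-based slice number on that axis.
#' @return A `slice_image` with fields `pixels`, `width`, `height`, `axis`,
#'   `index`.
#' @export
extract_slice <- function(volume, axis = c("y", "x", "z"), index) {
  stopifnot(inherits(volume, "voxel_volume"))
  axis <- match.arg(axis)
  a <- axis_index(axis)
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) ||
      index < 1L || index > volume$num[a]) {
    stop(sprintf("slice out of range: index %s not in [1, %d] on axis %s",
                 as.character(index), volume$num[a], axis))
  }
  v <- volume$intensities
  pixels <- switch(axis,
    x = array(v[index, , , drop = FALSE], dim(v)[2:3]),  # width = y, height = z
    y = array(v[, index, , drop = FALSE], dim(v)[c(1, 3)]),  # width = x, height = z
    z = array(v[, , index, drop = FALSE], dim(v)[1:2])   # width = x, height = y
  )
  structure(
    list(pixels = pixels, width = nrow(pixels), height = ncol(pixels),
         axis = axis, index = index),
    class = "slice_image"
  )
}

#' Restack slice images into a voxel volume
#'
#' Inverse of [extract_slice()] applied over all indices of one axis.
#'
#' @param slices list of `slice_image`s covering every index of `axis` once.
#' @param axis the axis perpendicular to the slices.
#' @param spacing,origin voxel geometry of the rebuilt volume.
#' @return A [voxel_volume()].
#' @export
stack_slices <- function(slices, axis = c("y", "x", "z"),
                         spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- axis_index(axis)
  idx <- vapply(slices, `[[`, 0L, "index")
  n <- length(slices)
  if (!setequal(idx, seq_len(n))) {
    stop("slices must cover indices 1..n exactly once")
  }
  w <- slices[[1]]$width; h <- slices[[1]]$height
  dims <- switch(axis, x = c(n, w, h), y = c(w, n, h), z = c(w, h, n))
  vol <- array(0, dim = dims)
  for (s in slices) {
    switch(axis,
      x = {vol[s$index, , ] <- s$pixels},
      y = {vol[, s$index, ] <- s$pixels},
      z = {vol[, , s$index] <- s$pixels})
  }
  voxel_volume(vol, spacing = spacing, origin = origin)
}

# ---- intensity normalization ------------------------------------------------

#' Min-max normalize a volume to the unit interval
#'
#' Per-volume min-max rescaling, the form of normalization expected by a
#' sigmoid-output segmentation network. A constant volume maps to all
#' zeros. Shape, spacing and origin are unchanged.
#'
#' @param volume a [voxel_volume()].
#' @return A [voxel_volume()] with intensities in `[0, 1]`.
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  v <- volume$intensities
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else array(0, dim(v))
  voxel_volume(v, spacing = volume$spacing, origin = volume$origin)
}

#' Crop a volume to the bounding box of a mask or intensity threshold
#'
#' Used to restrict a phantom series to the head itself so that per-axis
#' slice counts describe the scanned object, as a clinical head series does.
#'
#' @param volume a [voxel_volume()].
#' @param mask logical/0-1 array matching the grid; if `NULL`, voxels with
#'   intensity > `threshold` are used.
#' @param threshold intensity cutoff when `mask` is `NULL`.
#' @return The cropped [voxel_volume()] (origin shifted accordingly).
#' @export
crop_volume <- function(volume, mask = NULL, threshold = 0) {
  stopifnot(inherits(volume, "voxel_volume"))
  occ <- if (is.null(mask)) volume$intensities > threshold else mask != 0
  if (!any(occ)) stop("nothing to crop to: empty occupancy")
  idx <- which(occ, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub <- volume$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  voxel_volume(sub, spacing = volume$spacing,
               origin = volume$origin + (lo - 1L) * volume$spacing)
}

# ---- optional mask I/O ------------------------------------------------------

#' Export / import a binary mask volume as NIfTI
#'
#' Thin wrappers around `RNifti` for exchanging label volumes with external
#' tools.
#'
#' @param mask 0/1 3D array.
#' @param volume the [voxel_volume()] supplying voxel spacing.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `write_mask_nifti` invisibly returns `path`; `read_mask_nifti`
#'   returns an integer 0/1 array.
#' @export
write_mask_nifti <- function(mask, volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI mask export")
  }
  img <- RNifti::asNifti(array(as.integer(mask != 0), dim(mask)))
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI mask import")
  }
  arr <- as.array(RNifti::readNifti(path))
  array(as.integer(arr != 0), dim(arr))
}
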