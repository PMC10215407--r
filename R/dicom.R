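# Minimal single-frame DICOM codec: explicit/implicit VR little endian,
# uncompressed MONOCHROME2 16-bit pixel data. Covers exactly the dialect the
# phantom writer emits plus the tags load_dicom_series() needs; everything
# else is skipped structurally.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
.UID_ROOT <- "1.2.826.0.1.3680043.9.7484" # private example root

# ---- byte helpers -----------------------------------------------------------

u16le_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}

u32le_raw <- function(v) {
  v <- as.numeric(v)
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; b3 <- v %/% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}

read_u16le <- function(raw, n = 1L) {
  readBin(raw, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
}

read_u32le <- function(raw) {
  b <- as.integer(raw[1:4])
  b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# ---- element encoding (explicit VR little endian) ---------------------------

dcm_element <- function(group, element, vr, value_raw) {
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  header <- c(u16le_raw(group), u16le_raw(element), charToRaw(vr))
  if (long_form) {
    c(header, as.raw(c(0, 0)), u32le_raw(length(value_raw)), value_raw)
  } else {
    stopifnot(length(value_raw) <= 65535L)
    c(header, u16le_raw(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, element, vr, text) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  dcm_element(group, element, vr, pad_even(charToRaw(text), pad))
}

dcm_us <- function(group, element, value) {
  dcm_element(group, element, "US", u16le_raw(value))
}

fmt_ds <- function(x) paste(vapply(x, function(v) sprintf("%.10g", v), ""),
                            collapse = "\\")

dicom_uid <- function(suffix) paste0(.UID_ROOT, ".", suffix)

# ---- writer -----------------------------------------------------------------

# `pixels` is an integer matrix [rows, cols] in on-file order (row 1 = top).
write_dicom_file <- function(path, pixels, instance_number, position,
                             orientation, pixel_spacing, slice_spacing,
                             series_uid, study_uid) {
  if (any(pixels < 0L) || any(pixels > 65535L)) {
    stop("pixel values must lie in [0, 65535] for 16-bit DICOM output")
  }
  sop_uid <- dicom_uid(paste0(gsub("\\D", "", format(Sys.time(), "%Y%m%d")),
                              ".", instance_number, ".",
                              sample.int(1e6, 1L)))
  meta <- c(
    dcm_str(0x0002, 0x0002, "UI", .UID_CT_STORAGE),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE)
  )
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", .UID_CT_STORAGE),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0020, 0x000D, "UI", study_uid),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_str(0x0020, 0x0032, "DS", fmt_ds(position)),
    dcm_str(0x0020, 0x0037, "DS", fmt_ds(orientation)),
    dcm_str(0x0018, 0x0050, "DS", fmt_ds(slice_spacing)),
    dcm_str(0x0018, 0x0088, "DS", fmt_ds(slice_spacing)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(pixels)),
    dcm_us(0x0028, 0x0011, ncol(pixels)),
    dcm_str(0x0028, 0x0030, "DS", fmt_ds(pixel_spacing)),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 0L),
    # row-major on file: transpose the [row, col] matrix
    dcm_element(0x7FE0, 0x0010, "OW", u16le_raw(as.vector(t(pixels))))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_element(0x0002, 0x0000, "UL", u32le_raw(length(meta))), con)
  writeBin(meta, con)
  writeBin(dataset, con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

# Sequentially parses elements, returning a list keyed "GGGG,EEEE" with raw
# values. Stops after pixel data.
parse_dicom_elements <- function(bytes, pos, explicit, meta_only = FALSE) {
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- read_u16le(bytes[pos:(pos + 1L)])
    element <- read_u16le(bytes[(pos + 2L):(pos + 3L)])
    if (meta_only && group != 0x0002) break
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- read_u32le(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- read_u16le(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_u32le(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) stop("malformed series: undefined-length element")
    value <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- list(vr = vr, value = value)
    if (group == 0x7FE0 && element == 0x0010) break
  }
  out
}

dcm_value_str <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value[el$value != as.raw(0)]))
}

dcm_value_ds <- function(elements, key) {
  s <- dcm_value_str(elements, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_value_us <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  read_u16le(el$value, n = length(el$value) %/% 2L)[1L]
}

# Reads one single-frame file into a list of geometry fields + pixel matrix
# in on-file order [rows, cols].
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L) stop("malformed series: truncated file ", path)
  pos <- 1L
  if (rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
    meta_len_el <- parse_meta_group_length(bytes, pos)
    meta <- parse_dicom_elements(
      bytes, meta_len_el$pos, explicit = TRUE, meta_only = TRUE)
    ts <- dcm_value_str(meta, "0002,0010")
    if (is.null(ts)) ts <- .TS_EXPLICIT_LE
    pos <- meta_len_el$pos + meta_len_el$len
  } else {
    ts <- .TS_IMPLICIT_LE
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop("malformed series: unsupported transfer syntax ", ts)
  )
  el <- parse_dicom_elements(bytes, pos, explicit = explicit)
  rows <- dcm_value_us(el, "0028,0010")
  cols <- dcm_value_us(el, "0028,0011")
  bits <- dcm_value_us(el, "0028,0100")
  signed <- identical(dcm_value_us(el, "0028,0103"), 1L)
  px <- el[["7FE0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px)) {
    stop("malformed series: missing image geometry in ", path)
  }
  if (!identical(bits, 16L)) {
    stop("malformed series: only 16-bit pixel data is supported")
  }
  vals <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  list(
    pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
    rows = rows, cols = cols,
    instance = as.integer(dcm_value_str(el, "0020,0013")),
    position = dcm_value_ds(el, "0020,0032"),
    orientation = dcm_value_ds(el, "0020,0037"),
    pixel_spacing = dcm_value_ds(el, "0028,0030"),
    slice_spacing = dcm_value_ds(el, "0018,0088") %||%
      dcm_value_ds(el, "0018,0050")
  )
}

parse_meta_group_length <- function(bytes, pos) {
  group <- read_u16le(bytes[pos:(pos + 1L)])
  element <- read_u16le(bytes[(pos + 2L):(pos + 3L)])
  if (group != 0x0002 || element != 0x0000) {
    stop("malformed series: missing file meta group length")
  }
  len_field <- read_u16le(bytes[(pos + 6L):(pos + 7L)])
  list(pos = pos + 8L + len_field,
       len = read_u32le(bytes[(pos + 8L):(pos + 11L)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
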