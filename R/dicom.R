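# Minimal read-only DICOM support: uncompressed implicit- or explicit-VR
# little-endian transfer syntaxes, single-frame unsigned grayscale pixel
# data. Only the handful of Image Pixel attributes needed to decode the
# raster are looked at; every other element (in particular all patient and
# acquisition metadata) is skipped over and never stored.

DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"
DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs that use a 2-byte reserved field + 4-byte length in explicit encoding.
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

read_u32 <- function(raw, pos) {
  # doubles, to survive lengths >= 2^31 (0xFFFFFFFF marks undefined length)
  sum(as.numeric(raw[pos + 0:3]) * c(1, 256, 65536, 16777216))
}

read_dicom_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("unsupported format: '%s' has no DICM marker", path),
         call. = FALSE)
  }
  pos <- 133L

  # File meta group (0002,xxxx) is always explicit VR little endian.
  syntax <- DICOM_EXPLICIT_LE
  while (pos + 7L <= length(raw)) {
    group <- read_u16(raw, pos)
    if (group != 2L) break
    el <- parse_element(raw, pos, explicit = TRUE)
    if (el$element == 0x0010 && group == 2L) {
      syntax <- trimws(rawToChar(el$value[el$value != as.raw(0L)]))
    }
    pos <- el$next_pos
  }
  if (!syntax %in% c(DICOM_IMPLICIT_LE, DICOM_EXPLICIT_LE)) {
    stop(sprintf("unsupported DICOM transfer syntax '%s': only uncompressed little-endian data can be read",
                 syntax), call. = FALSE)
  }
  explicit <- identical(syntax, DICOM_EXPLICIT_LE)

  fields <- list(rows = NULL, cols = NULL, bits_allocated = NULL,
                 pixel_representation = 0L, samples_per_pixel = 1L,
                 n_frames = 1L, pixel_data = NULL)
  while (pos + 7L <= length(raw)) {
    group <- read_u16(raw, pos)
    el <- parse_element(raw, pos, explicit = explicit)
    pos <- el$next_pos
    if (group == 0x0028) {
      v <- el$value
      if (el$element == 0x0002) fields$samples_per_pixel <- read_u16(v, 1L)
      if (el$element == 0x0008) {
        fields$n_frames <- suppressWarnings(as.integer(trimws(rawToChar(v))))
      }
      if (el$element == 0x0010) fields$rows <- read_u16(v, 1L)
      if (el$element == 0x0011) fields$cols <- read_u16(v, 1L)
      if (el$element == 0x0100) fields$bits_allocated <- read_u16(v, 1L)
      if (el$element == 0x0103) fields$pixel_representation <- read_u16(v, 1L)
    } else if (group == 0x7FE0 && el$element == 0x0010) {
      fields$pixel_data <- el$value
      break
    }
    # anything else -- including every metadata element -- is dropped here
  }

  if (is.null(fields$rows) || is.null(fields$cols) ||
      is.null(fields$bits_allocated) || is.null(fields$pixel_data)) {
    stop(sprintf("unsupported format: '%s' lacks a decodable grayscale pixel raster",
                 path), call. = FALSE)
  }
  if (fields$samples_per_pixel != 1L) {
    stop(sprintf("unsupported format: '%s' has %d samples per pixel; a single-channel grayscale image is required",
                 path, fields$samples_per_pixel), call. = FALSE)
  }
  if (!is.na(fields$n_frames) && fields$n_frames > 1L) {
    stop(sprintf("unsupported format: '%s' is multi-frame (%d frames)",
                 path, fields$n_frames), call. = FALSE)
  }
  if (fields$pixel_representation != 0L) {
    stop(sprintf("unsupported format: '%s' stores signed pixel data", path),
         call. = FALSE)
  }

  n <- fields$rows * fields$cols
  v <- fields$pixel_data
  if (fields$bits_allocated <= 8L) {
    if (length(v) < n) stop("truncated DICOM pixel data", call. = FALSE)
    vals <- as.integer(v[seq_len(n)])
    depth <- 8L
  } else if (fields$bits_allocated == 16L) {
    if (length(v) < 2L * n) stop("truncated DICOM pixel data", call. = FALSE)
    idx <- seq.int(1L, by = 2L, length.out = n)
    vals <- as.integer(v[idx]) + 256L * as.integer(v[idx + 1L])
    depth <- 16L
  } else {
    stop(sprintf("unsupported DICOM bits allocated: %d",
                 fields$bits_allocated), call. = FALSE)
  }
  # DICOM pixel data is stored row by row
  gray_image(matrix(vals, fields$rows, fields$cols, byrow = TRUE), depth)
}

# Parse one data element starting at `pos`; returns element number, value
# bytes and the position just past the element.
parse_element <- function(raw, pos, explicit) {
  element <- read_u16(raw, pos + 2L)
  if (explicit) {
    vr <- rawToChar(raw[pos + 4:5])
    if (vr %in% LONG_VRS) {
      len <- read_u32(raw, pos + 8L)
      start <- pos + 12L
    } else {
      len <- read_u16(raw, pos + 6L)
      start <- pos + 8L
    }
    if (identical(vr, "SQ") || len >= 4294967295) {
      stop("unsupported DICOM element: sequences/undefined lengths cannot be read",
           call. = FALSE)
    }
  } else {
    len <- read_u32(raw, pos + 4L)
    start <- pos + 8L
    if (len >= 4294967295) {
      stop("unsupported DICOM element: sequences/undefined lengths cannot be read",
           call. = FALSE)
    }
  }
  len <- as.integer(len)
  value <- if (len > 0L) raw[start + 0:(len - 1L)] else raw[0L]
  list(element = element, value = value, next_pos = start + len)
}
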