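#' Load a grayscale radiograph
#'
#' Reads a single-frame grayscale raster from a DICOM, PNG, or TIFF file and
#' returns only the pixel matrix and container bit depth. For DICOM input
#' the entire header (patient and acquisition metadata) is parsed only as
#' far as needed to locate the pixel data and is then discarded: the
#' returned [gray_image] has no metadata slot of any kind.
#'
#' The bit depth is inferred from the stored sample depth of the container
#' (stored depth \eqn{\le} 8 gives 8, anything larger gives 16), never from
#' the observed pixel maximum, so dark images are not misclassified.
#'
#' @param path Path to an existing image file.
#' @param format Optional format tag, one of `"png"`, `"tiff"`, `"dicom"`.
#'   By default the format is sniffed from the file's magic bytes.
#' @return A [gray_image].
#' @seealso [save_image()]
#' @export
load_grayscale <- function(path, format = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'",
                 as.character(path)[1L]), call. = FALSE)
  }
  if (is.null(format)) format <- sniff_format(path)
  format <- match.arg(tolower(format), c("png", "tiff", "dicom"))
  switch(format,
    png = load_png(path),
    tiff = load_tiff(path),
    dicom = read_dicom_gray(path)
  )
}

# Identify a file by its magic bytes (PNG signature, TIFF II*/MM*, DICM at
# byte offset 128).
sniff_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 132L)
  if (length(head) >= 8L &&
      identical(head[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                    0x0d, 0x0a, 0x1a, 0x0a)))) {
    return("png")
  }
  if (length(head) >= 4L &&
      (identical(head[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
       identical(head[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a))))) {
    return("tiff")
  }
  if (length(head) >= 132L &&
      identical(rawToChar(head[129:132]), "DICM")) {
    return("dicom")
  }
  stop(sprintf("unsupported image format: '%s' is not PNG, TIFF, or DICOM",
               path), call. = FALSE)
}

load_png <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (length(dim(arr)) == 3L) {
    stop(sprintf("unsupported format: '%s' is a color PNG (%d channels); a single-channel grayscale image is required",
                 path, dim(arr)[3L]), call. = FALSE)
  }
  depth <- if (!is.null(info$bit.depth) && info$bit.depth > 8L) 16L else 8L
  lim <- bitwShiftL(1L, depth) - 1L
  gray_image(round(arr * lim), depth)
}

load_tiff <- function(path) {
  raw <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (is.list(raw)) {
    if (length(raw) > 1L) {
      stop(sprintf("unsupported format: '%s' contains %d frames; a single-frame image is required",
                   path, length(raw)), call. = FALSE)
    }
    raw <- raw[[1L]]
  }
  if (length(dim(raw)) == 3L) {
    stop(sprintf("unsupported format: '%s' is a color TIFF (%d channels); a single-channel grayscale image is required",
                 path, dim(raw)[3L]), call. = FALSE)
  }
  depth <- if (max(raw) > 255L) 16L else infer_tiff_depth(path)
  gray_image(raw, depth)
}

# Stored sample depth from the TIFF directory, independent of pixel values.
infer_tiff_depth <- function(path) {
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) NULL)
  bits <- if (is.list(info)) info[["bits.per.sample"]] else NULL
  if (is.null(bits)) 8L else if (max(bits) > 8L) 16L else 8L
}

#' Save a grayscale image to PNG or TIFF
#'
#' Writes the raster losslessly: loading the written file with
#' [load_grayscale()] reproduces the pixels bit-exactly. PNG output is
#' 8-bit only; writing a 16-bit image to PNG is an error rather than a
#' silent truncation. TIFF output uses the image's own bit depth.
#'
#' @param img A [gray_image].
#' @param path Destination path.
#' @param format `"png"` or `"tiff"`; by default inferred from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, format = NULL) {
  assert_gray_image(img)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, png = "png", tif = , tiff = "tiff",
                     stop(sprintf("cannot infer output format from extension '.%s'; pass `format`", ext),
                          call. = FALSE))
  }
  format <- match.arg(tolower(format), c("png", "tiff"))
  lim <- max_level(img)
  ok <- switch(format,
    png = {
      if (img$bit_depth > 8L) {
        stop("cannot store a 16-bit image in an 8-bit PNG container; use TIFF",
             call. = FALSE)
      }
      try(png::writePNG(img$pixels / lim, path), silent = TRUE)
    },
    tiff = try(tiff::writeTIFF(img$pixels / lim, path,
                               bits.per.sample = img$bit_depth),
               silent = TRUE)
  )
  if (inherits(ok, "try-error")) {
    stop(sprintf("cannot write image to '%s'", path), call. = FALSE)
  }
  invisible(path)
}
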