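#' Grayscale image container
#'
#' A `gray_image` holds a 2-D non-negative integer intensity raster together
#' with its declared bit depth. All pixel values must satisfy
#' `0 <= v <= 2^bit_depth - 1`. The bit depth describes the storage
#' container, not the occupied dynamic range: a dark 16-bit radiograph whose
#' maximum pixel happens to fall below 256 is still a 16-bit image.
#'
#' Row/column indices reported by the rest of the package (bounds, centroids,
#' the central column) are 0-based, matching the usual image-processing
#' convention; bounding intervals are inclusive on both ends.
#'
#' @param pixels Integer (or losslessly coercible numeric) matrix of
#'   intensities, row-major raster with at least 2 rows and 2 columns.
#' @param bit_depth Either `8` or `16`.
#' @return An object of class `gray_image` with fields `pixels` (integer
#'   matrix) and `bit_depth`.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2), bit_depth = 8)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels)) {
    stop("`pixels` must be a matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("a gray_image needs at least 2 rows and 2 columns", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  storage <- pixels
  if (!is.integer(storage)) {
    if (any(abs(storage - round(storage)) > 1e-9)) {
      stop("pixel values must be integers", call. = FALSE)
    }
    storage <- matrix(as.integer(round(storage)), nrow(pixels), ncol(pixels))
  }
  if (anyNA(storage)) stop("pixel values must not be NA", call. = FALSE)
  lim <- bitwShiftL(1L, bit_depth) - 1L
  rng <- range(storage)
  if (rng[1L] < 0L || rng[2L] > lim) {
    stop(sprintf("pixel values must lie in [0, %d] for bit depth %d",
                 lim, bit_depth), call. = FALSE)
  }
  structure(list(pixels = storage, bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  rng <- range(x$pixels)
  cat(sprintf("<gray_image> %d x %d, %d-bit, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, rng[1L], rng[2L]))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(x, arg = "img") {
  if (!is_gray_image(x)) {
    stop(sprintf("`%s` must be a gray_image", arg), call. = FALSE)
  }
  invisible(x)
}

max_level <- function(img) bitwShiftL(1L, img$bit_depth) - 1L

#' Image complement
#'
#' Computes `C(i, j) = max(A) - A(i, j)`. Digital X-ray detectors receive
#' less intensity behind dense objects, so bone appears dark; the complement
#' restores the familiar film convention (dense = bright) and anchors the
#' histogram origin at 0 regardless of the occupied dynamic range: the
#' minimum of the output is exactly 0 for every input.
#'
#' Applying `complement()` twice yields `A - min(A)`, i.e. the original
#' image shifted so its minimum is 0.
#'
#' @param img A [gray_image].
#' @return A [gray_image] of the same dimensions and bit depth.
#' @examples
#' complement(gray_image(matrix(c(0, 5, 10, 10), 2, 2), 8))$pixels
#' @export
complement <- function(img) {
  assert_gray_image(img)
  gray_image(max(img$pixels) - img$pixels, img$bit_depth)
}

#' Occupied dynamic range of an image
#'
#' Raw radiographs typically occupy only a small, dark slice of the
#' container depth; this reports the exact minimum and maximum gray level
#' present, the quantity plotted in the package's diagnostics report.
#'
#' @param img A [gray_image].
#' @return Named integer vector `c(min = ..., max = ...)`.
#' @examples
#' dynamic_range(gray_image(matrix(c(3, 5, 9, 7), 2, 2), 8))
#' @export
dynamic_range <- function(img) {
  assert_gray_image(img)
  rng <- range(img$pixels)
  c(min = rng[1L], max = rng[2L])
}
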