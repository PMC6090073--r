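#' Intensity histogram of a grayscale image
#'
#' Counts pixels at every gray level of the container range
#' `0 .. 2^bit_depth - 1`. The counts always sum to the number of pixels in
#' the source image (conservation), which is the invariant most tests lean
#' on. Internally the histogram is dense over the full depth range; the
#' tabular/CSV exports report only occupied levels.
#'
#' @param img A [gray_image].
#' @return An `intensity_histogram`: list with `counts` (integer vector
#'   indexed by level + 1), `total`, `bit_depth`, and a `cumulative` flag.
#' @examples
#' h <- compute_histogram(gray_image(matrix(c(0, 0, 1, 2), 2, 2), 8))
#' h$counts[1:3]  # levels 0, 1, 2
#' @export
compute_histogram <- function(img) {
  assert_gray_image(img)
  nlev <- bitwShiftL(1L, img$bit_depth)
  counts <- tabulate(as.vector(img$pixels) + 1L, nbins = nlev)
  new_histogram(counts, img$bit_depth, cumulative = FALSE)
}

new_histogram <- function(counts, bit_depth, cumulative) {
  total <- if (cumulative) counts[length(counts)] else sum(counts)
  structure(list(counts = as.integer(counts), total = as.integer(total),
                 bit_depth = as.integer(bit_depth),
                 cumulative = isTRUE(cumulative)),
            class = "intensity_histogram")
}

assert_histogram <- function(h) {
  if (!inherits(h, "intensity_histogram")) {
    stop("expected an intensity_histogram", call. = FALSE)
  }
  invisible(h)
}

#' Cumulative histogram
#'
#' Running sum of the per-level counts; the final entry equals the total
#' pixel count and the sequence is non-decreasing in the gray level.
#'
#' @param h An `intensity_histogram` as returned by [compute_histogram()].
#' @return An `intensity_histogram` with `cumulative = TRUE`.
#' @export
cumulative <- function(h) {
  assert_histogram(h)
  if (h$cumulative) return(h)
  new_histogram(cumsum(h$counts), h$bit_depth, cumulative = TRUE)
}

#' Dynamic threshold at a histogram quantile
#'
#' Gray-level ranges vary strongly from radiograph to radiograph, so a fixed
#' binarization cut cannot suit every image; instead the threshold is taken
#' from the image's own histogram. The default `fraction = 0.25` places it
#' at the first quartile: the smallest gray level `t` whose cumulative count
#' reaches `ceiling(fraction * total)`. On the complement image the darkest
#' quarter of pixels -- in practice the background -- then falls at or below
#' `t`. Ties and plateaus resolve to the smallest qualifying level, so the
#' result is deterministic, and the threshold is monotone non-decreasing in
#' `fraction`.
#'
#' @param h An `intensity_histogram` (plain or cumulative).
#' @param fraction Proportion of pixels to place at or below the threshold,
#'   strictly between 0 and 1.
#' @return The threshold gray level (integer).
#' @examples
#' img <- gray_image(matrix(c(rep(0, 3), rep(10, 5), rep(200, 8)), 4, 4), 8)
#' quartile_threshold(compute_histogram(img))  # 10
#' @export
quartile_threshold <- function(h, fraction = 0.25) {
  assert_histogram(h)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (h$total <= 0L) {
    stop("cannot take a quantile of an empty histogram", call. = FALSE)
  }
  cum <- if (h$cumulative) h$counts else cumsum(h$counts)
  target <- ceiling(fraction * h$total)
  which(cum >= target)[1L] - 1L
}

#' Turn a histogram into a tibble of occupied levels
#'
#' @param x An `intensity_histogram`.
#' @param ... Unused.
#' @return A tibble with columns `level` and `count`, one row per gray
#'   level with a nonzero count.
#' @export
tidy.intensity_histogram <- function(x, ...) {
  keep <- if (x$cumulative) x$counts > 0L | seq_along(x$counts) == 1L
          else x$counts > 0L
  tibble::tibble(level = which(keep) - 1L, count = x$counts[keep])
}

#' Export a histogram as a two-column CSV
#'
#' Writes `level,count` rows for the occupied gray levels, the format used
#' by the diagnostics report.
#'
#' @param h An `intensity_histogram`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(h, path) {
  assert_histogram(h)
  utils::write.csv(as.data.frame(tidy.intensity_histogram(h)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram%s> %d-bit, %d pixels, %d occupied levels\n",
              if (x$cumulative) " (cumulative)" else "",
              x$bit_depth, x$total, sum(x$counts > 0L)))
  invisible(x)
}

#' Plot an intensity histogram
#'
#' @param object An `intensity_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intensity_histogram <- function(object, ...) {
  df <- tidy.intensity_histogram(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::labs(
      x = "gray level",
      y = if (object$cumulative) "cumulative pixel count" else "pixel count"
    ) +
    ggplot2::theme_minimal()
}
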