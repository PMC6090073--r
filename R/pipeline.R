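#' Crop an image to ROI bounds
#'
#' @param img A [gray_image].
#' @param bounds An [roi_bounds]; must lie within the image.
#' @return A [gray_image] with dimensions
#'   `(bottom - top + 1) x (right - left + 1)`.
#' @export
crop <- function(img, bounds) {
  assert_gray_image(img)
  if (!inherits(bounds, "roi_bounds")) {
    stop("`bounds` must be an roi_bounds", call. = FALSE)
  }
  d <- dim(img$pixels)
  if (bounds$bottom > d[1L] - 1L || bounds$right > d[2L] - 1L) {
    stop(sprintf("bounds (%d, %d) exceed image dimensions %d x %d",
                 bounds$bottom, bounds$right, d[1L], d[2L]), call. = FALSE)
  }
  gray_image(img$pixels[(bounds$top:bounds$bottom) + 1L,
                        (bounds$left:bounds$right) + 1L, drop = FALSE],
             img$bit_depth)
}

#' Size reduction of an ROI relative to its source image
#'
#' `100 * (1 - roi_pixels / original_pixels)`, the headline diagnostic of
#' the method: full-height neck crops typically remove 30-60 % of the
#' pixels while keeping the cervical area intact.
#'
#' @param original,roi [gray_image]s; `roi` must be no larger than
#'   `original` in either dimension.
#' @return The reduction percentage (0 to just below 100).
#' @export
reduction_percent <- function(original, roi) {
  assert_gray_image(original, "original")
  assert_gray_image(roi, "roi")
  if (nrow(roi$pixels) > nrow(original$pixels) ||
      ncol(roi$pixels) > ncol(original$pixels)) {
    stop("`roi` must be no larger than `original` in both dimensions",
         call. = FALSE)
  }
  100 * (1 - length(roi$pixels) / length(original$pixels))
}

#' Histogram equalization onto the full container range
#'
#' Cropping to the ROI usually leaves a narrow occupied gray-level band, so
#' contrast is enhanced by the standard cumulative-distribution remapping
#' `out(g) = round((cdf(g) - cdf_min) / (N - cdf_min) * (2^bit_depth - 1))`,
#' where `cdf_min` is the smallest nonzero cumulative count. The mapping is
#' monotone non-decreasing (rank order of gray levels is preserved) and for
#' any input with at least two distinct levels the output attains both 0
#' and `2^bit_depth - 1`, i.e. the full 0-255 or 0-65535 scale. The mapping
#' is computed from the image's own histogram; pipeline callers pass the
#' cropped ROI, never the full image. A constant image is returned
#' unchanged with a warning (the mapping is undefined).
#'
#' @param img A [gray_image].
#' @return A [gray_image] of the same dimensions and bit depth.
#' @export
equalize <- function(img) {
  assert_gray_image(img)
  lim <- max_level(img)
  h <- tabulate(as.vector(img$pixels) + 1L, nbins = lim + 1L)
  cdf <- cumsum(h)
  n <- length(img$pixels)
  cdf_min <- min(cdf[cdf > 0L])
  if (cdf_min == n) {
    warning("constant image: histogram equalization is undefined, returning input unchanged",
            call. = FALSE)
    return(img)
  }
  map <- as.integer(round((cdf - cdf_min) / (n - cdf_min) * lim))
  map[map < 0L] <- 0L
  gray_image(matrix(map[img$pixels + 1L], nrow(img$pixels), ncol(img$pixels)),
             img$bit_depth)
}

#' Run the full ROI-extraction pipeline
#'
#' Executes, in order: image complement (unless `apply_complement = FALSE`
#' for images already in dense-is-bright convention), intensity histogram,
#' dynamic threshold at the `fraction` quantile (first quartile by
#' default), binarization, 8-connected labeling, largest-object selection,
#' silhouette isolation, narrowest-span boundary detection about the
#' silhouette's centroid column, a full-height crop of the complement
#' image, and histogram equalization of the crop. Deterministic for fixed
#' input and options.
#'
#' @param img A [gray_image] in digital X-ray convention (dense anatomy
#'   dark) unless `apply_complement = FALSE`.
#' @param fraction Threshold quantile, strictly between 0 and 1; the
#'   default 0.25 is the first quartile. Raising it never widens the crop
#'   and eventually cuts into the cervical area -- see the package vignette.
#' @param apply_complement Apply the Stage-2 complement? Set to `FALSE`
#'   when the input already has dense anatomy bright.
#' @param keep_mask Also return the isolated silhouette mask.
#' @return A `cerv_roi` object: list with `roi_image` (the equalized crop),
#'   `bounds`, `threshold`, `fraction`, `center_col`, `reduction_percent`,
#'   `input_range`, `roi_range_before_eq`, `silhouette` (object features),
#'   and optionally `mask`.
#' @examples
#' ph <- generate_phantom(phantom_spec(rows = 128, cols = 128, seed = 1))
#' res <- run_pipeline(ph$image)
#' res$reduction_percent
#' @export
run_pipeline <- function(img, fraction = 0.25, apply_complement = TRUE,
                         keep_mask = FALSE) {
  assert_gray_image(img)
  work <- if (isTRUE(apply_complement)) complement(img) else img
  h <- compute_histogram(work)
  threshold <- quartile_threshold(h, fraction)
  mask <- binarize(work, threshold)
  labm <- label_matrix(mask)           # labeled once, reused for isolation
  objects <- features_from_labels(labm)
  silhouette <- tryCatch(
    largest_object(objects),
    cervroi_no_silhouette = function(c) {
      stop_cervroi("no_silhouette", conditionMessage(c),
                   stage = "largest_object")
    }
  )
  iso <- binary_mask(labm == silhouette$label)
  center_col <- as.integer(floor(silhouette$centroid_col + 0.5))
  bounds <- tryCatch(
    detect_bounds(iso, center_col),
    cervroi_no_neck = function(c) {
      stop_cervroi("no_neck", conditionMessage(c), stage = "detect_bounds")
    }
  )
  roi_raw <- crop(work, bounds)
  roi <- equalize(roi_raw)
  structure(list(
    roi_image = roi,
    bounds = bounds,
    threshold = threshold,
    fraction = fraction,
    center_col = center_col,
    reduction_percent = reduction_percent(img, roi),
    input_range = dynamic_range(img),
    roi_range_before_eq = dynamic_range(roi_raw),
    silhouette = silhouette,
    mask = if (isTRUE(keep_mask)) iso else NULL
  ), class = "cerv_roi")
}

#' @export
print.cerv_roi <- function(x, ...) {
  cat(sprintf(
    "<cerv_roi> threshold %d (fraction %.2f), cols %d..%d of %s, reduction %.1f%%\n",
    x$threshold, x$fraction, x$bounds$left, x$bounds$right,
    "full-height strip", x$reduction_percent))
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x A `cerv_roi` result.
#' @param ... Unused.
#' @return A one-row tibble with the bounds, threshold, central column,
#'   reduction percentage, and dynamic ranges.
#' @export
tidy.cerv_roi <- function(x, ...) {
  tibble::tibble(
    input_min = x$input_range[["min"]],
    input_max = x$input_range[["max"]],
    threshold = x$threshold,
    fraction = x$fraction,
    top = x$bounds$top, bottom = x$bounds$bottom,
    left = x$bounds$left, right = x$bounds$right,
    center_col = x$center_col,
    roi_min_before_eq = x$roi_range_before_eq[["min"]],
    roi_max_before_eq = x$roi_range_before_eq[["max"]],
    reduction_percent = x$reduction_percent
  )
}

#' One-row summary of a pipeline result
#'
#' @param x A `cerv_roi` result.
#' @param ... Unused.
#' @return A one-row tibble: threshold, ROI dimensions, reduction.
#' @export
glance.cerv_roi <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    roi_rows = nrow(x$roi_image$pixels),
    roi_cols = ncol(x$roi_image$pixels),
    reduction_percent = x$reduction_percent
  )
}

#' Plot the extracted ROI
#'
#' @param object A `cerv_roi` result.
#' @param ... Unused.
#' @return A ggplot raster of the equalized ROI.
#' @export
autoplot.cerv_roi <- function(object, ...) {
  px <- object$roi_image$pixels
  df <- data.frame(
    row = rep(seq_len(nrow(px)) - 1L, times = ncol(px)),
    col = rep(seq_len(ncol(px)) - 1L, each = nrow(px)),
    value = as.vector(px)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, max_level(object$roi_image))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "level") +
    ggplot2::theme_minimal()
}

#' Diagnostics table over pipeline results
#'
#' One row per image with the occupied input dynamic range, threshold,
#' bounds, and reduction percentage -- the per-image quantities a batch run
#' reports for quality control.
#'
#' @param results A `cerv_roi` or a list of them.
#' @param path Optional CSV destination; when given the table is also
#'   written there.
#' @return A tibble with one row per result.
#' @export
diagnostics_report <- function(results, path = NULL) {
  if (inherits(results, "cerv_roi")) results <- list(results)
  if (length(results) < 1L) {
    stop("`results` must contain at least one pipeline result",
         call. = FALSE)
  }
  rows <- lapply(results, tidy.cerv_roi)
  out <- do.call(rbind, rows)
  out <- tibble::as_tibble(out)
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(out), path, row.names = FALSE,
                     quote = FALSE)
  }
  out
}
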