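#' Crop bounds of the region of interest
#'
#' Inclusive rectangle `(top, left)`–`(bottom, right)` in 0-based
#' coordinates. Bounds produced by [detect_bounds()] always span the full
#' image height (`top = 0`, `bottom = rows - 1`); only the columns are
#' narrowed, to the silhouette's narrowest (neck) span.
#'
#' @param top,bottom First and last row (0-based, `top <= bottom`).
#' @param left,right First and last column (0-based, `left <= right`).
#' @return An object of class `roi_bounds`.
#' @export
roi_bounds <- function(top, bottom, left, right) {
  v <- vapply(list(top, bottom, left, right), function(x) {
    if (!is.numeric(x) || length(x) != 1L || x < 0 || x != round(x)) {
      stop("bounds must be single non-negative integers", call. = FALSE)
    }
    as.integer(x)
  }, integer(1L))
  if (v[1L] > v[2L] || v[3L] > v[4L]) {
    stop("bounds must satisfy top <= bottom and left <= right",
         call. = FALSE)
  }
  structure(list(top = v[1L], bottom = v[2L], left = v[3L], right = v[4L]),
            class = "roi_bounds")
}

#' @export
print.roi_bounds <- function(x, ...) {
  cat(sprintf("<roi_bounds> rows %d..%d, cols %d..%d (0-based, inclusive)\n",
              x$top, x$bottom, x$left, x$right))
  invisible(x)
}

#' Background-run scan: boundary column of the narrowest row
#'
#' Restricted to the column window `[start_col, end_col]`, finds the row
#' with the maximum number of zero cells (ties resolve to the smallest row
#' index) and scans that row left to right. With `flag = 0` it returns the
#' column of the first cell whose predecessor is 0 and which is itself 1 --
#' the object's left edge; with `flag = 1`, the column of the last cell that
#' is 1 and whose successor is 0 -- the object's right edge. Predecessor and
#' successor are taken within the window.
#'
#' The mask should be the isolated silhouette: on a single-component mask
#' the selected row has exactly one qualifying transition per side, and the
#' returned column is the outermost object column of the narrowest row, so
#' the eventual crop never cuts into the object.
#'
#' @param mask A [binary_mask], normally from [isolate_object()].
#' @param start_col,end_col Window columns, 0-based inclusive,
#'   `0 <= start_col <= end_col <= cols - 1`.
#' @param flag 0 to search for the 0-to-1 change (left edge), 1 for the
#'   1-to-0 change (right edge).
#' @return The 0-based column index of the transition.
#' @examples
#' m <- binary_mask(rbind(c(1, 1, 1, 1, 1, 1),
#'                        c(0, 1, 1, 1, 1, 0),
#'                        c(0, 0, 1, 1, 0, 0),
#'                        c(0, 1, 1, 1, 1, 0)))
#' count_max_zeros(m, 0, 3, 0)  # row 2 has most zeros; left edge at col 2
#' count_max_zeros(m, 3, 5, 1)  # right edge at col 3
#' @export
count_max_zeros <- function(mask, start_col, end_col, flag) {
  assert_mask(mask)
  nc <- ncol(mask)
  if (!all(c(start_col, end_col) == round(c(start_col, end_col))) ||
      start_col < 0L || end_col < start_col || end_col > nc - 1L) {
    stop(sprintf("column window must satisfy 0 <= start_col <= end_col <= %d",
                 nc - 1L), call. = FALSE)
  }
  win <- unclass(mask)[, (start_col + 1L):(end_col + 1L), drop = FALSE]
  zeros <- ncol(win) - rowSums(win)
  row <- which.max(zeros)            # first maximum: smallest row index
  r <- win[row, ]
  n <- length(r)
  if (flag == 0L) {
    hits <- which(r[-1L] == 1L & r[-n] == 0L) + 1L
    if (length(hits) == 0L) {
      stop_cervroi("no_neck", sprintf(
        "no 0-to-1 transition in row %d of window [%d, %d]: degenerate silhouette",
        row - 1L, start_col, end_col))
    }
    start_col + hits[1L] - 1L
  } else if (flag == 1L) {
    hits <- which(r[-n] == 1L & r[-1L] == 0L)
    if (length(hits) == 0L) {
      stop_cervroi("no_neck", sprintf(
        "no 1-to-0 transition in row %d of window [%d, %d]: degenerate silhouette",
        row - 1L, start_col, end_col))
    }
    start_col + hits[length(hits)] - 1L
  } else {
    stop("`flag` must be 0 or 1", call. = FALSE)
  }
}

#' Left and right crop columns at the silhouette's narrowest span
#'
#' Splits the mask at the virtual boundary `center_col` (the rounded
#' centroid column of the silhouette) and runs [count_max_zeros()] on each
#' half: the left half `[0, center_col]` searched for the 0-to-1 edge, the
#' right half `[center_col, cols - 1]` for the 1-to-0 edge. The two halves
#' select their narrowest rows independently, so the rows may differ. The
#' returned bounds keep the full image height -- the vertical extent is left
#' at the original image values so no vertical information is lost -- and
#' satisfy `left <= center_col <= right`.
#'
#' @param mask The isolated-silhouette [binary_mask].
#' @param center_col 0-based central column, `0 < center_col < cols - 1`;
#'   use `floor(centroid_col + 0.5)` of the largest object.
#' @return An [roi_bounds].
#' @export
detect_bounds <- function(mask, center_col) {
  assert_mask(mask)
  nc <- ncol(mask)
  if (!is.numeric(center_col) || length(center_col) != 1L ||
      center_col != round(center_col) ||
      center_col <= 0L || center_col >= nc - 1L) {
    stop(sprintf("`center_col` must be an integer in (0, %d)", nc - 1L),
         call. = FALSE)
  }
  left <- count_max_zeros(mask, 0L, center_col, 0L)
  right <- count_max_zeros(mask, center_col, nc - 1L, 1L)
  stopifnot(left <= center_col, center_col <= right)
  roi_bounds(0L, nrow(mask) - 1L, left, right)
}
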