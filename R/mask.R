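#' Binary mask container
#'
#' A `binary_mask` is a `{0, 1}` raster of the same dimensions as its source
#' image: 1 marks object, 0 marks background.
#'
#' @param cells Matrix of 0/1 (or logical) values.
#' @return A `binary_mask` (integer matrix with a class attribute).
#' @export
binary_mask <- function(cells) {
  if (!is.matrix(cells)) stop("`cells` must be a matrix", call. = FALSE)
  if (is.logical(cells)) {
    m <- matrix(as.integer(cells), nrow(cells), ncol(cells))
  } else {
    if (!all(cells %in% c(0L, 1L))) {
      stop("a binary_mask may contain only 0 and 1", call. = FALSE)
    }
    m <- matrix(as.integer(cells), nrow(cells), ncol(cells))
  }
  structure(m, class = c("binary_mask", "matrix", "array"))
}

assert_mask <- function(mask) {
  if (!inherits(mask, "binary_mask")) {
    stop("expected a binary_mask", call. = FALSE)
  }
  invisible(mask)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground cells\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Binarize an image at a threshold
#'
#' Cells strictly above `t` become 1, all others 0. The strict rule matters:
#' with the first-quartile cut applied to the complement image, every pixel
#' of the darkest quarter -- the background -- lands at 0, which is what the
#' downstream background-run scan counts. The foreground count is monotone
#' non-increasing in `t`.
#'
#' @param img A [gray_image].
#' @param t Threshold gray level within the container range.
#' @return A [binary_mask].
#' @examples
#' binarize(gray_image(matrix(c(0, 5, 10, 200), 2, 2), 8), 10)
#' @export
binarize <- function(img, t) {
  assert_gray_image(img)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > max_level(img)) {
    stop(sprintf("threshold must lie in [0, %d]", max_level(img)),
         call. = FALSE)
  }
  binary_mask(img$pixels > t)
}

# 8-connected component labeling. Returns an integer matrix: 0 background,
# components numbered 1..k in raster order of their first pixel.
label_matrix <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask == 1L)              # linear (column-major) indices
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(out)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)

  is_fg <- mask == 1L
  edges <- list()
  # neighbor offsets: right, down, down-right, up-right (covers all 8-conn
  # pairs once)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    rows <- seq_len(nr - abs(dr))
    if (dr < 0L) rows <- rows + abs(dr)
    cols <- seq_len(nc - dc)
    a <- is_fg[rows, cols, drop = FALSE] &
         is_fg[rows + dr, cols + dc, drop = FALSE]
    if (any(a)) {
      hit <- which(a)
      r0 <- ((hit - 1L) %% length(rows)) + 1L
      c0 <- ((hit - 1L) %/% length(rows)) + 1L
      from <- (cols[c0] - 1L) * nr + rows[r0]
      to <- (cols[c0] + dc - 1L) * nr + rows[r0] + dr
      edges[[length(edges) + 1L]] <- rbind(id[from], id[to])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  memb <- igraph::components(g)$membership

  # relabel deterministically: by raster order (row-major) of first pixel
  r <- ((fg - 1L) %% nr)
  cc <- ((fg - 1L) %/% nr)
  first_raster <- tapply(r * nc + cc, memb, min)
  relabel <- integer(length(first_raster))
  relabel[order(first_raster)] <- seq_along(first_raster)
  out[fg] <- relabel[memb]
  out
}

#' Connected-object features of a binary mask
#'
#' Labels the 8-connected components of the 1-cells and reports one row per
#' object: pixel area, centroid, and inclusive bounding box. Diagonally
#' touching pixels belong to the same object. Row/column coordinates are
#' 0-based. The areas always sum to the number of 1-cells.
#'
#' @param mask A [binary_mask].
#' @return A tibble with columns `label`, `area`, `centroid_row`,
#'   `centroid_col`, `top`, `left`, `bottom`, `right`; zero rows for an
#'   all-background mask.
#' @export
label_objects <- function(mask) {
  assert_mask(mask)
  features_from_labels(label_matrix(mask))
}

features_from_labels <- function(lab) {
  fg <- which(lab > 0L)
  if (length(fg) == 0L) {
    return(tibble::tibble(label = integer(), area = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          top = integer(), left = integer(),
                          bottom = integer(), right = integer()))
  }
  nr <- nrow(lab)
  r0 <- (fg - 1L) %% nr          # 0-based row
  c0 <- (fg - 1L) %/% nr         # 0-based col
  m <- lab[fg]
  tibble::tibble(
    label = sort(unique(m)),
    area = as.integer(tabulate(m)),
    centroid_row = as.numeric(tapply(r0, m, mean)),
    centroid_col = as.numeric(tapply(c0, m, mean)),
    top = as.integer(tapply(r0, m, min)),
    left = as.integer(tapply(c0, m, min)),
    bottom = as.integer(tapply(r0, m, max)),
    right = as.integer(tapply(c0, m, max))
  )
}

#' Select the largest object (the patient silhouette)
#'
#' After quartile binarization the patient silhouette is by far the largest
#' connected object; picking it discards stray blobs such as labels,
#' collimator edges, or background speckle. Ties on area break to the
#' smallest `(top, left)` bounding-box corner and then the smallest label,
#' so the choice is deterministic.
#'
#' @param objects Tibble from [label_objects()].
#' @return The one-row tibble of the selected object.
#' @export
largest_object <- function(objects) {
  if (!is.data.frame(objects)) {
    stop("`objects` must be the data frame returned by label_objects()",
         call. = FALSE)
  }
  if (nrow(objects) == 0L) {
    stop_cervroi("no_silhouette",
                 "no object found: thresholding produced an empty mask")
  }
  ord <- order(-objects$area, objects$top, objects$left, objects$label)
  objects[ord[1L], , drop = FALSE]
}

#' Erase everything except one object
#'
#' Zeroes every component of the mask other than `object`, so the boundary
#' scan downstream operates on the isolated silhouette and stray blobs
#' cannot corrupt transition detection.
#'
#' @param mask The [binary_mask] the object was labeled from.
#' @param object A one-row tibble from [label_objects()]/[largest_object()].
#' @return A [binary_mask] whose 1-cells are exactly the object's component.
#' @export
isolate_object <- function(mask, object) {
  assert_mask(mask)
  if (!is.data.frame(object) || nrow(object) != 1L) {
    stop("`object` must be a single object-feature row", call. = FALSE)
  }
  lab <- label_matrix(mask)
  keep <- lab == object$label
  if (sum(keep) != object$area) {
    stop("stale object: the given features were not produced from this mask",
         call. = FALSE)
  }
  binary_mask(keep)
}

#' Write a mask as a black-and-white PNG
#'
#' Foreground cells map to 255, background to 0; intended for visual
#' inspection of the binarization stage.
#'
#' @param mask A [binary_mask].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  assert_mask(mask)
  save_image(gray_image(unclass(mask) * 255L, 8L), path, format = "png")
}
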