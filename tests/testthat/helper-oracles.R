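# Independent brute-force oracles. These are deliberately naive (loops,
# explicit enumeration) so they share no code path with the package.

# 8-connected components by explicit flood fill; returns a list of sorted
# linear-index vectors, one per component, ordered by first pixel in
# row-major raster order.
flood_fill_components <- function(cells) {
  nr <- nrow(cells)
  nc <- ncol(cells)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      if (cells[r, cl] == 1L && !seen[r, cl]) {
        stack <- list(c(r, cl))
        seen[r, cl] <- TRUE
        members <- integer()
        while (length(stack) > 0L) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          members <- c(members, (p[2L] - 1L) * nr + p[1L])
          for (dr in -1:1) for (dc in -1:1) {
            rr <- p[1L] + dr; cc <- p[2L] + dc
            if ((dr != 0L || dc != 0L) && rr >= 1L && rr <= nr &&
                cc >= 1L && cc <= nc && cells[rr, cc] == 1L &&
                !seen[rr, cc]) {
              seen[rr, cc] <- TRUE
              stack[[length(stack) + 1L]] <- c(rr, cc)
            }
          }
        }
        comps[[length(comps) + 1L]] <- sort(members)
      }
    }
  }
  comps
}

# Exhaustive re-statement of the narrowest-row boundary scan: enumerate
# every row's zero count in the window, take the first row attaining the
# maximum, list every transition explicitly, then pick first 0->1 (flag 0)
# or last 1->0 (flag 1). Returns the 0-based column, or the string
# "no-transition".
count_max_zeros_oracle <- function(cells, start_col, end_col, flag) {
  zero_counts <- integer(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    z <- 0L
    for (cl in (start_col + 1L):(end_col + 1L)) {
      if (cells[r, cl] == 0L) z <- z + 1L
    }
    zero_counts[r] <- z
  }
  best <- which(zero_counts == max(zero_counts))[1L]
  cols01 <- integer()
  cols10 <- integer()
  pairs <- if (end_col > start_col) (start_col + 1L):end_col else integer()
  for (cl in pairs) {
    a <- cells[best, cl]; b <- cells[best, cl + 1L]
    if (a == 0L && b == 1L) cols01 <- c(cols01, cl)      # col of the 1 (0-based)
    if (a == 1L && b == 0L) cols10 <- c(cols10, cl - 1L) # col of the 1 (0-based)
  }
  if (flag == 0L) {
    if (length(cols01) == 0L) return("no-transition")
    cols01[1L]
  } else {
    if (length(cols10) == 0L) return("no-transition")
    cols10[length(cols10)]
  }
}

# Random single-8-connected-component mask built by seeded blob growth.
random_blob_mask <- function(nr, nc, size) {
  cells <- matrix(0L, nr, nc)
  r <- sample.int(nr, 1L)
  cl <- sample.int(nc, 1L)
  cells[r, cl] <- 1L
  frontier <- matrix(c(r, cl), 1L, 2L)
  while (sum(cells) < size) {
    pick <- frontier[sample.int(nrow(frontier), 1L), ]
    dr <- sample(-1:1, 1L); dc <- sample(-1:1, 1L)
    rr <- pick[1L] + dr; cc <- pick[2L] + dc
    if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
        cells[rr, cc] == 0L) {
      cells[rr, cc] <- 1L
      frontier <- rbind(frontier, c(rr, cc))
    }
  }
  binary_mask(cells)
}

random_raster <- function(nr, nc, bit_depth = 8L) {
  lim <- bitwShiftL(1L, bit_depth) - 1L
  gray_image(matrix(sample(0:lim, nr * nc, replace = TRUE), nr, nc),
             bit_depth)
}

# The worked 4 x 6 example used across the boundary-detection tests.
micro_mask <- function() {
  binary_mask(rbind(c(1, 1, 1, 1, 1, 1),
                    c(0, 1, 1, 1, 1, 0),
                    c(0, 0, 1, 1, 0, 0),
                    c(0, 1, 1, 1, 1, 0)))
}
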