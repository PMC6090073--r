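test_that("histogram counts pixels per level and conserves the total", {
  h <- compute_histogram(gray_image(rbind(c(0L, 1L), c(0L, 2L)), 8L))
  expect_identical(h$counts[1:3], c(2L, 1L, 1L))
  expect_identical(h$total, 4L)
  expect_identical(sum(h$counts), h$total)

  # constant image: a single bin holding every pixel
  h1 <- compute_histogram(gray_image(matrix(42L, 10, 10), 8L))
  expect_identical(h1$counts[43L], 100L)
  expect_identical(sum(h1$counts > 0L), 1L)

  for (seed in 1:5) {
    set.seed(seed)
    img <- random_raster(13, 7)
    expect_identical(sum(compute_histogram(img)$counts),
                     length(img$pixels))
  }
})

test_that("cumulative histogram is the running sum, non-decreasing, ending at total", {
  img <- gray_image(matrix(c(0L, 0L, 1L, 2L), 2, 2), 8L)
  cum <- cumulative(compute_histogram(img))
  expect_identical(cum$counts[1:3], c(2L, 3L, 4L))
  expect_true(all(diff(cum$counts) >= 0L))
  expect_identical(cum$counts[length(cum$counts)], cum$total)
  set.seed(9)
  h <- compute_histogram(random_raster(20, 20))
  cc <- cumulative(h)
  expect_true(all(diff(cc$counts) >= 0L))
  expect_identical(cc$counts[length(cc$counts)], h$total)
})

test_that("quartile threshold is the smallest level reaching ceil(fraction * N)", {
  # counts {0: 3, 10: 5, 200: 8}: target 4, cum(0) = 3 < 4, cum(10) = 8 >= 4
  img <- gray_image(matrix(c(rep(0L, 3), rep(10L, 5), rep(200L, 8)), 4, 4),
                    8L)
  h <- compute_histogram(img)
  expect_identical(quartile_threshold(h, 0.25), 10L)
  # degenerate: everything at level 0
  h0 <- compute_histogram(gray_image(matrix(0L, 4, 4), 8L))
  expect_identical(quartile_threshold(h0, 0.25), 0L)
  # counts {0: 2, 9: 2} at fraction 0.5: cum(0) = 2 >= 2, so t = 0
  h2 <- compute_histogram(gray_image(matrix(c(0L, 0L, 9L, 9L), 2, 2), 8L))
  expect_identical(quartile_threshold(h2, 0.5), 0L)
  expect_error(quartile_threshold(h2, 1.0), "between 0 and 1")
  expect_error(quartile_threshold(h2, 0), "between 0 and 1")
})

test_that("quartile threshold matches a sort-based quantile oracle and is monotone in fraction", {
  for (seed in 1:20) {
    set.seed(seed)
    img <- random_raster(11, 9, sample(c(8L, 16L), 1L))
    h <- compute_histogram(img)
    fracs <- sort(runif(4, 0.05, 0.95))
    ts <- vapply(fracs, function(f) {
      t_pkg <- quartile_threshold(h, f)
      # oracle: the ceil(f * N)-th smallest pixel value
      sorted <- sort(as.vector(img$pixels))
      expect_identical(t_pkg, sorted[ceiling(f * length(sorted))])
      t_pkg
    }, integer(1L))
    expect_true(all(diff(ts) >= 0L))
  }
})

test_that("dynamic range reports the exact occupied extremes", {
  expect_identical(dynamic_range(gray_image(rbind(c(3L, 9L), c(5L, 7L)), 8L)),
                   c(min = 3L, max = 9L))
  expect_identical(dynamic_range(gray_image(matrix(6L, 3, 3), 8L)),
                   c(min = 6L, max = 6L))
  set.seed(2)
  comp <- complement(random_raster(6, 6))
  expect_identical(dynamic_range(comp)[["min"]], 0L)
})

test_that("histogram CSV export writes level,count rows for occupied levels", {
  img <- gray_image(matrix(c(0L, 0L, 5L, 200L), 2, 2), 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(compute_histogram(img), path)
  got <- utils::read.csv(path)
  expect_identical(got$level, c(0L, 5L, 200L))
  expect_identical(got$count, c(2L, 1L, 1L))
})
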