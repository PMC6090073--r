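test_that("the worked 4 x 6 example reproduces the hand enumeration", {
  m <- micro_mask()
  # left half [0, 3]: row 2 has the most zeros (2); first 0->1 at column 2
  expect_identical(count_max_zeros(m, 0L, 3L, 0L), 2L)
  # right half [3, 5]: row 2 again; last 1->0 leaves the object at column 3
  expect_identical(count_max_zeros(m, 3L, 5L, 1L), 3L)
  b <- detect_bounds(m, 3L)
  expect_identical(c(b$top, b$bottom, b$left, b$right), c(0L, 3L, 2L, 3L))
})

test_that("an all-ones window has no transition and signals no-neck", {
  m <- binary_mask(matrix(1L, 4, 6))
  expect_error(count_max_zeros(m, 0L, 3L, 0L), class = "cervroi_no_neck")
})

test_that("count_max_zeros agrees with the exhaustive oracle on random masks", {
  agree <- 0L
  n_cases <- 120L
  for (seed in seq_len(n_cases)) {
    set.seed(seed)
    mask <- random_blob_mask(8L, 12L, sample(6:40, 1L))
    start <- sample(0:10, 1L)
    end <- sample(start:11, 1L)
    flag <- sample(0:1, 1L)
    got <- tryCatch(count_max_zeros(mask, start, end, flag),
                    cervroi_no_neck = function(c) "no-transition")
    want <- count_max_zeros_oracle(unclass(mask), start, end, flag)
    expect_identical(got, want)
    agree <- agree + identical(got, want)
  }
  expect_identical(agree, n_cases)
})

test_that("detect_bounds is equivariant under horizontal mirroring", {
  for (seed in 1:10) {
    set.seed(seed)
    # blob straddling the centre so both halves see background and object
    mask <- random_blob_mask(10L, 16L, 60L)
    nc <- ncol(mask)
    m_c <- 8L
    b <- tryCatch(detect_bounds(mask, m_c),
                  cervroi_no_neck = function(c) NULL)
    mirrored <- binary_mask(unclass(mask)[, nc:1])
    bm <- tryCatch(detect_bounds(mirrored, nc - 1L - m_c),
                   cervroi_no_neck = function(c) NULL)
    if (is.null(b)) {
      expect_null(bm)
    } else {
      expect_identical(bm$left, nc - 1L - b$right)
      expect_identical(bm$right, nc - 1L - b$left)
    }
  }
})

test_that("bounds always bracket the centre column and keep full height", {
  ph <- generate_phantom(phantom_spec(rows = 96, cols = 96, seed = 4))
  res <- run_pipeline(ph$image)
  expect_identical(res$bounds$top, 0L)
  expect_identical(res$bounds$bottom, 95L)
  expect_true(res$bounds$left <= res$center_col)
  expect_true(res$center_col <= res$bounds$right)
  # the returned window contains the silhouette's narrowest row span
  expect_true(res$bounds$left <= ph$neck_left)
  expect_true(res$bounds$right >= ph$neck_right)
})

test_that("roi_bounds validates its ordering invariants", {
  expect_error(roi_bounds(3, 1, 0, 5), "top <= bottom")
  expect_error(roi_bounds(0, 1, 5, 2), "left <= right")
  expect_error(roi_bounds(-1, 1, 0, 2), "non-negative")
})
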