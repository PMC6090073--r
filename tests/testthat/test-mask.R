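test_that("binarize uses the strict greater-than rule", {
  img <- gray_image(rbind(c(0L, 10L), c(5L, 200L)), 8L)
  expect_identical(unclass(binarize(img, 10L))[, ],
                   rbind(c(0L, 0L), c(0L, 1L)))
  expect_identical(sum(binarize(img, max(img$pixels))), 0L)
  img2 <- gray_image(rbind(c(0L, 1L), c(1L, 0L)), 8L)
  expect_identical(unclass(binarize(img2, 0L))[, ],
                   rbind(c(0L, 1L), c(1L, 0L)))
})

test_that("foreground count is monotone non-increasing in the threshold", {
  set.seed(5)
  img <- random_raster(15, 15)
  counts <- vapply(seq(0L, 255L, by = 15L),
                   function(t) sum(binarize(img, t)), integer(1L))
  expect_true(all(diff(counts) <= 0L))
})

test_that("labeling matches a flood-fill oracle on random small masks", {
  for (seed in 1:25) {
    set.seed(seed)
    cells <- matrix(rbinom(20 * 20, 1L, 0.4), 20, 20)
    mask <- binary_mask(cells)
    objs <- label_objects(mask)
    oracle <- flood_fill_components(cells)
    expect_identical(nrow(objs), length(oracle))
    expect_identical(sum(objs$area), sum(cells))  # conservation
    # pixel-exact partition: isolate each object and compare to the oracle
    # component covering the same pixels
    nr <- nrow(cells)
    oracle_keys <- vapply(oracle, function(v) paste(v, collapse = ","),
                          character(1L))
    for (k in seq_len(nrow(objs))) {
      iso <- isolate_object(mask, objs[k, ])
      got <- paste(sort(which(unclass(iso) == 1L)), collapse = ",")
      expect_true(got %in% oracle_keys)
    }
  }
})

test_that("object features report area, centroid, and inclusive bbox", {
  cells <- matrix(0L, 5, 5)
  cells[2:4, 2:4] <- 1L
  objs <- label_objects(binary_mask(cells))
  expect_identical(nrow(objs), 1L)
  expect_identical(objs$area, 9L)
  expect_equal(objs$centroid_row, 2)   # 0-based
  expect_equal(objs$centroid_col, 2)
  expect_identical(c(objs$top, objs$left, objs$bottom, objs$right),
                   c(1L, 1L, 3L, 3L))

  # diagonally touching pixels are one object under 8-connectivity
  diagonal <- matrix(0L, 4, 4)
  diagonal[1, 1] <- 1L
  diagonal[2, 2] <- 1L
  expect_identical(nrow(label_objects(binary_mask(diagonal))), 1L)

  # all-background mask: empty feature table
  empty <- label_objects(binary_mask(matrix(0L, 3, 3)))
  expect_identical(nrow(empty), 0L)
})

test_that("largest_object picks maximum area with deterministic tie-breaks", {
  cells <- matrix(0L, 10, 10)
  cells[1:3, 1:3] <- 1L      # area 9
  cells[6:7, 6:8] <- 1L      # area 6
  cells[9, 1:5] <- 1L        # area 5
  objs <- label_objects(binary_mask(cells))
  expect_identical(largest_object(objs)$area, 9L)

  # equal areas: the object with the smaller bbox top wins
  tie <- matrix(0L, 10, 4)
  tie[1:2, 1:2] <- 1L
  tie[6:7, 1:2] <- 1L
  best <- largest_object(label_objects(binary_mask(tie)))
  expect_identical(best$top, 0L)

  expect_error(largest_object(label_objects(binary_mask(matrix(0L, 3, 3)))),
               class = "cervroi_no_silhouette")
})

test_that("isolate_object keeps exactly the chosen component", {
  cells <- matrix(0L, 8, 8)
  cells[1:4, 1:4] <- 1L
  cells[7:8, 7:8] <- 1L
  mask <- binary_mask(cells)
  objs <- label_objects(mask)
  big <- largest_object(objs)
  iso <- isolate_object(mask, big)
  expect_identical(sum(iso), big$area)
  expect_identical(sum(unclass(iso)[7:8, 7:8]), 0L)

  # single-component mask is returned unchanged
  solo <- binary_mask(matrix(1L, 3, 3))
  expect_identical(unclass(isolate_object(solo,
                                          label_objects(solo)[1, ]))[, ],
                   unclass(solo)[, ])

  # stale features from a different mask are refused
  other <- binary_mask(matrix(c(1L, rep(0L, 8)), 3, 3))
  expect_error(isolate_object(other, big), "stale")
})
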