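test_that("phantom generation is byte-identical for a fixed seed", {
  spec <- phantom_spec(rows = 96, cols = 96, seed = 17)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(c(a$neck_left, a$neck_right),
                   c(b$neck_left, b$neck_right))
  # a different seed changes the noise realisation
  c2 <- generate_phantom(phantom_spec(rows = 96, cols = 96, seed = 18))
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("phantom invariants are enforced", {
  expect_error(phantom_spec(neck_halfwidth_frac = 0.48),
               "narrower than the shoulders")
  expect_error(phantom_spec(neck_halfwidth_frac = 0.45,
                            shoulder_halfwidth_frac = 0.46),
               "narrower than the head")
  expect_error(phantom_spec(background_level_frac = 0.7),
               "background < rim < tissue < bone")
  expect_error(phantom_spec(bone_core_halfwidth_frac = 0.3),
               "bone core")
})

test_that("the phantom is in digital X-ray convention with the stated bands", {
  ph <- generate_phantom(phantom_spec(rows = 128, cols = 128, seed = 3,
                                      noise_sd_frac = 0))
  px <- ph$image$pixels
  # background (corner) is bright, neck tissue darker, bone core darkest
  centre_row <- 64L
  expect_gt(px[1L, 1L], px[centre_row, ph$neck_left + 3L])
  expect_gt(px[centre_row, ph$neck_left + 3L], px[centre_row, 64L])
  # ground-truth columns delimit the band: just outside is background
  expect_gt(px[centre_row, ph$neck_left - 1L], px[centre_row, ph$neck_left + 1L])
})

test_that("suite phantoms are reproducible and span both depths", {
  s1 <- generate_suite(4, seed = 7, rows = 96L, cols = 96L)
  s2 <- generate_suite(4, seed = 7, rows = 96L, cols = 96L)
  expect_identical(length(s1), 4L)
  for (i in seq_along(s1)) {
    expect_identical(s1[[i]]$image$pixels, s2[[i]]$image$pixels)
  }
  both <- generate_suite(2, seed = 5, bit_depths = c(8L, 16L),
                         rows = 96L, cols = 96L)
  expect_identical(length(both), 4L)
  depths <- vapply(both, function(p) p$spec$bit_depth, integer(1L))
  expect_setequal(depths, c(8L, 16L))
  # matched geometry across depths shares the ground truth
  expect_identical(both[[1L]]$neck_left, both[[3L]]$neck_left)
  expect_identical(both[[2L]]$neck_right, both[[4L]]$neck_right)
})

test_that("single-phantom suite and n validation behave", {
  expect_identical(length(generate_suite(1, seed = 1, rows = 96L,
                                         cols = 96L)), 1L)
  expect_error(generate_suite(0, seed = 1), "positive")
})
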