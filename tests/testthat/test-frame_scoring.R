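uniform_frame <- function(rgb, h = 8, w = 8) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("pixel classification follows the HSV rule on uniform frames", {
  cfg <- classifier_config()
  # mid-pink mucosa: hue ~343, outside the dirty band
  pink <- uniform_frame(c(0.90, 0.62, 0.70))
  expect_false(any(classify_pixels(pink, cfg)))
  # saturated yellow-brown: hue 40, s .75, v .60 -> inside the band
  brown <- uniform_frame(c(0.60, 0.45, 0.15))
  expect_true(all(classify_pixels(brown, cfg)))
  # same hue but too dark fails the value threshold
  dark <- uniform_frame(c(0.10, 0.075, 0.025))
  expect_false(any(classify_pixels(dark, cfg)))
  # same hue but washed out fails the saturation threshold
  washed <- uniform_frame(c(0.80, 0.75, 0.65))
  expect_false(any(classify_pixels(washed, cfg)))
})

test_that("classification is deterministic and handles band wrap and 0-255 input", {
  f <- generate_frame_image(0.4, size = 24, seed = 42)
  m1 <- classify_pixels(f$image)
  m2 <- classify_pixels(f$image)
  expect_identical(m1, m2)
  # integer-scaled input gives the same mask
  expect_identical(classify_pixels(f$image * 255), m1)
  # a wrapped band through 0 degrees catches the pink background instead
  wrap <- classifier_config(hue_band = c(300, 10), saturation_min = 0.1)
  pink <- uniform_frame(c(0.90, 0.62, 0.70))
  expect_true(all(classify_pixels(pink, wrap)))
})

test_that("classifier recovers the generator's ground-truth mask exactly", {
  for (f in c(0, 0.3, 0.77, 1)) {
    gen <- generate_frame_image(f, size = 64, seed = 11)
    mask <- classify_pixels(gen$image)
    expect_identical(unclass(mask), unclass(gen$mask))
    expect_equal(clean_fraction(mask), 1 - gen$n_dirty / (64 * 64))
  }
})

test_that("clean_fraction and the dirty complement partition the frame", {
  m <- matrix(FALSE, 10, 10)
  m[sample.int(100, 37)] <- TRUE
  expect_equal(clean_fraction(m), 0.63)
  expect_equal(clean_fraction(m) + mean(m), 1)
  expect_equal(clean_fraction(matrix(FALSE, 3, 3)), 1)
  expect_equal(clean_fraction(matrix(TRUE, 3, 3)), 0)
  expect_equal(clean_dirty_ratio(m), 63 / 37)
  expect_identical(clean_dirty_ratio(matrix(FALSE, 2, 2)), Inf)
  expect_error(clean_fraction(logical(0)), class = "ccecleanse_input_error")
})

test_that("invalid frames are rejected", {
  expect_error(classify_pixels(matrix(0.5, 4, 4)), class = "ccecleanse_input_error")
  expect_error(classify_pixels(array(0.5, c(4, 4, 2))), class = "ccecleanse_input_error")
  expect_error(classify_pixels(array(NA_real_, c(2, 2, 3))),
               class = "ccecleanse_input_error")
})

test_that("fraction_to_rating is the clamped affine map", {
  expect_equal(fraction_to_rating(0), 1)
  expect_equal(fraction_to_rating(0.5), 3)
  r1 <- fraction_to_rating(1)
  expect_lt(r1, 5)
  expect_equal(floor(r1), 4)
  grid <- seq(0, 1, by = 0.001)
  r <- fraction_to_rating(grid)
  expect_true(all(diff(r) >= 0))
  expect_true(all(floor(r) %in% 1:4))
  expect_error(fraction_to_rating(-0.1), class = "ccecleanse_input_error")
  expect_error(fraction_to_rating(1.1), class = "ccecleanse_input_error")
})

test_that("score_frames reads a frame directory in lexicographic order", {
  dir <- withr::local_tempdir()
  fracs <- c(0.8, 0.1, 0.5)
  for (i in seq_along(fracs)) {
    gen <- generate_frame_image(fracs[i], size = 16, seed = i)
    png::writePNG(gen$image, file.path(dir, sprintf("frame_%03d.png", i)))
  }
  sc <- score_frames(dir)
  expect_equal(sc$frame_index, 0:2)
  expect_equal(sc$clean_fraction, 1 - round(fracs * 256) / 256)
  expect_equal(sc$rating, fraction_to_rating(sc$clean_fraction))

  # CSV round trip at the declared 6-decimal precision
  sc$video_id <- "vidA"
  sc$timestamp_s <- sc$frame_index / 5
  path <- file.path(dir, "scores.csv")
  write_frame_scores(sc, path)
  back <- read_frame_scores(path)
  expect_equal(back$rating, sc$rating, tolerance = 1e-6)
  expect_equal(back$clean_fraction, sc$clean_fraction, tolerance = 1e-6)
  expect_identical(back$video_id, sc$video_id)
})
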