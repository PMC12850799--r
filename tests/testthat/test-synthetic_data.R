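test_that("frame generator hits the requested dirty area exactly", {
  expect_equal(generate_frame_image(0, size = 16, seed = 1)$n_dirty, 0)
  expect_true(all(generate_frame_image(1, size = 16, seed = 1)$mask))
  g <- generate_frame_image(0.3, size = 256, seed = 2)
  expect_equal(g$n_dirty, round(0.3 * 65536))
  expect_equal(sum(g$mask), 19661)
  # pure function of (arguments, seed)
  g2 <- generate_frame_image(0.3, size = 256, seed = 2)
  expect_identical(g$image, g2$image)
  expect_error(generate_frame_image(1.2, 16), class = "ccecleanse_input_error")
})

test_that("noiseless rating streams sit exactly at the grade-cell midpoints", {
  b <- segment_boundaries(c(10, 25, 60, 80), "five", n_frames = 100)
  st <- generate_rating_stream(c(2, 1, 4, 3, 2), b, 100, noise = 0, seed = 5)
  expect_equal(nrow(st), 100)
  expect_identical(unique(st$rating[st$segment == "cecum"]), 2.5)
  expect_identical(unique(st$rating[st$segment == "transverse"]), 4.5)
  # every statistic floors back to the latent grade
  for (seg in c("cecum", "right", "transverse", "left", "rectum")) {
    lat <- attr(st, "latents")[[seg]]
    g <- grade_all_stats(st$rating[st$segment == seg])
    expect_true(all(g$grade == lat))
  }
  expect_equal(st$clean_fraction, (st$rating - 1) / 4)
})

test_that("rating streams are seeded, bounded and validated", {
  b <- segment_boundaries(c(30, 60), "three", n_frames = 90)
  s1 <- generate_rating_stream(c(2, 3, 4), b, 90, noise = 0.8, seed = 7)
  s2 <- generate_rating_stream(c(2, 3, 4), b, 90, noise = 0.8, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$rating >= 1 & s1$rating < 5))
  expect_error(generate_rating_stream(c(0, 3, 4), b, 90),
               class = "ccecleanse_input_error")
  expect_error(generate_rating_stream(c(2, 3), b, 90),
               class = "ccecleanse_input_error")
})

test_that("median grading recovers the latent grade under moderate noise", {
  b <- segment_boundaries(c(500, 1500), "three", n_frames = 2000)
  hits <- vapply(1:200, function(s) {
    st <- generate_rating_stream(c(3, 3, 3), b, 2000, noise = 0.4, seed = s)
    grade_scope(st$rating, "median")$grade == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("reader reports follow the confusion matrix", {
  lat <- c(2, 1, 4, 3, 2)
  rep1 <- generate_reader_report(lat, diag(4), seed = 1)
  expect_identical(unname(rep1$grades), as.integer(lat))

  bad <- matrix(0.3, 4, 4)
  expect_error(generate_reader_report(lat, bad), class = "ccecleanse_config_error")

  # uniform rows decouple reports from latents: kappa near zero
  unif <- matrix(0.25, 4, 4)
  withr::with_seed(13, {
    lats <- sample.int(4, 2000, replace = TRUE)
    reported <- vapply(seq_along(lats), function(i) {
      generate_reader_report(rep(lats[i], 5), unif, seed = i)$grades[[1]]
    }, integer(1))
    k <- cohen_kappa(build_contingency(lats, reported, k = 4))$kappa
    expect_lt(abs(k), 0.06)
  })
})

test_that("adjacent-grade reader confusion favors weighted over unweighted kappa", {
  conf <- matrix(0, 4, 4)
  for (i in 1:4) {
    adj <- intersect(c(i - 1, i + 1), 1:4)
    conf[i, i] <- 0.7
    conf[i, adj] <- 0.3 / length(adj)
  }
  withr::with_seed(14, {
    lats <- sample.int(4, 5000, replace = TRUE)
    reported <- vapply(lats, function(g) {
      sample.int(4, 1, prob = conf[g, ])
    }, integer(1))
    t <- build_contingency(lats, reported, k = 4)
    expect_gt(weighted_kappa(t, "linear")$kappa, cohen_kappa(t)$kappa)
  })
})

test_that("cohorts are pure functions of (config, seed) and write consistent files", {
  cfg <- cohort_config(n_videos = 3, frames_range = c(30, 50))
  c1 <- generate_cohort(cfg, seed = 99)
  c2 <- generate_cohort(cfg, seed = 99)
  expect_identical(c1$frame_scores, c2$frame_scores)
  expect_identical(c1$reader_reports, c2$reader_reports)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, seed = 99, dir = d1)
  generate_cohort(cfg, seed = 99, dir = d2)
  for (f in c("frame_scores.csv", "reader_reports.csv", "ground_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  # single-video cohort keeps identifiers consistent everywhere
  one <- generate_cohort(cohort_config(n_videos = 1, frames_range = c(20, 20)),
                         seed = 2)
  expect_identical(unique(one$frame_scores$video_id), "vid0001")
  expect_identical(one$reader_reports$video_id, "vid0001")
  expect_identical(one$ground_truth[[1]]$video_id, "vid0001")
  expect_equal(nrow(one$frame_scores), 20)
  # boundaries are interior and increasing
  b <- unlist(one$reader_reports[c("b_cecum_end", "b_hepatic", "b_splenic",
                                   "b_rectosigmoid")])
  expect_true(all(diff(b) > 0) && b[1] > 0 && b[4] < 20)
})

test_that("rendered image-mode cohorts are classifiable end to end", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_videos = 1, frames_range = c(6, 6), noise = 0.6)
  generate_cohort(cfg, seed = 8, dir = dir, write_frames = TRUE,
                  frame_size = 16)
  files <- list.files(file.path(dir, "frames", "vid0001"), full.names = TRUE)
  expect_length(files, 6)
  sc <- score_frames(file.path(dir, "frames", "vid0001"))
  stored <- read_frame_scores(file.path(dir, "frame_scores.csv"))
  # recovered clean fraction matches the stored one to the 16x16 pixel grid
  expect_equal(sc$clean_fraction, stored$clean_fraction, tolerance = 1 / 256)
})
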