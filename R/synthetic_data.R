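# Synthetic study data: frame images with ground-truth masks, per-frame
# rating streams with segment structure, and correlated reader reports.

DIRTY_RGB <- c(0.60, 0.45, 0.15)  # yellow-brown, hue 40, s 0.75, v 0.60
MUCOSA_RGB <- c(0.90, 0.62, 0.70) # pink, hue ~343, s 0.31, v 0.90

#' Generate a synthetic capsule frame with ground-truth mask
#'
#' Paints hard-edged yellow-brown residue blobs on a pink mucosa background.
#' The dirty area is the closest achievable pixel count to `dirty_fraction`
#' (exactly `round(dirty_fraction * n_pixels)` pixels), so the default
#' [classifier_config()] recovers the stored mask pixel for pixel: blob hues
#' lie inside, and the background hue outside, the default dirty band. Pixel
#' brightness is jittered multiplicatively, which perturbs HSV value only,
#' never hue or saturation.
#'
#' @param dirty_fraction target dirty-pixel share in `[0, 1]`.
#' @param size frame side length in pixels (square frame), or `c(height,
#'   width)`.
#' @param seed RNG seed; the frame is a pure function of the arguments.
#' @param n_blobs number of residue blob centers.
#' @return list with `image` (height x width x 3 array on `[0, 1]`), `mask`
#'   (`pixel_mask`, `TRUE` = dirty) and `n_dirty` (ground-truth dirty count).
#' @examples
#' f <- generate_frame_image(0.3, size = 32, seed = 7)
#' clean_fraction(f$mask)
#' @export
generate_frame_image <- function(dirty_fraction, size = 64, seed = 1,
                                 n_blobs = 6) {
  if (!is.numeric(dirty_fraction) || length(dirty_fraction) != 1L ||
      is.na(dirty_fraction) || dirty_fraction < 0 || dirty_fraction > 1) {
    input_error("`dirty_fraction` must be a single value in [0, 1]")
  }
  if (length(size) == 1L) size <- c(size, size)
  if (!all(vapply(size, is_count, logical(1)))) {
    input_error("`size` must be positive integer dimensions")
  }
  h <- as.integer(size[1]); w <- as.integer(size[2])
  npix <- h * w
  n_dirty <- round(dirty_fraction * npix)

  with_seed(seed, {
    # Blob potential: sum of Gaussians at random centers; threshold at the
    # n_dirty-th largest value for an exact pixel count. Tiny jitter breaks
    # ties deterministically.
    cy <- stats::runif(n_blobs, 1, h)
    cx <- stats::runif(n_blobs, 1, w)
    rad <- stats::runif(n_blobs, min(h, w) / 8, min(h, w) / 3)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    pot <- matrix(0, h, w)
    for (b in seq_len(n_blobs)) {
      pot <- pot + exp(-((yy - cy[b])^2 + (xx - cx[b])^2) / (2 * rad[b]^2))
    }
    pot <- pot + stats::runif(npix, 0, 1e-9)

    dirty <- matrix(FALSE, h, w)
    if (n_dirty > 0) {
      dirty[order(pot, decreasing = TRUE)[seq_len(n_dirty)]] <- TRUE
    }

    img <- array(0, dim = c(h, w, 3))
    bg_jit <- 1 + stats::runif(npix, -0.03, 0.03)
    fg_jit <- 1 + stats::runif(npix, -0.05, 0.05)
    for (ch in 1:3) {
      plane <- MUCOSA_RGB[ch] * bg_jit
      plane[dirty] <- (DIRTY_RGB[ch] * fg_jit)[dirty]
      img[, , ch] <- pmin(pmax(matrix(plane, h, w), 0), 1)
    }
    list(image = img,
         mask = structure(dirty, class = c("pixel_mask", "matrix")),
         n_dirty = n_dirty)
  })
}

# Truncated-normal frame ratings on [1, 5): inverse-CDF sampling so that
# noise = 0 degenerates exactly to the center.
rtrunc_ratings <- function(n, center, noise) {
  lo <- 1
  hi <- 5 - 1e-6
  if (noise == 0) return(rep(min(max(center, lo), hi), n))
  a <- stats::pnorm(lo, center, noise)
  b <- stats::pnorm(hi, center, noise)
  stats::qnorm(stats::runif(n, a, b), center, noise)
}

#' Generate a per-frame rating stream with segment structure
#'
#' Frame ratings are drawn per segment from a normal distribution truncated to
#' `[1, 5)`, centered at `latent grade + 0.5` — the midpoint of the grade
#' cell, so with `noise = 0` every summary statistic floors back to the latent
#' grade exactly.
#'
#' @param latents integer latent grades in 1-4, one per segment (3 or 5,
#'   matching `boundaries$mode`).
#' @param boundaries a [segment_boundaries()] object.
#' @param n_frames total frame count.
#' @param noise standard deviation of the within-segment rating distribution
#'   (>= 0, rating units).
#' @param seed RNG seed.
#' @param fps frames per second used to derive timestamps.
#' @return data.frame with `frame_index` (0-based), `timestamp_s`,
#'   `clean_fraction`, `rating`, `segment`; the latent grades are kept in
#'   `attr(, "latents")`.
#' @export
generate_rating_stream <- function(latents, boundaries, n_frames,
                                   noise = 0.5, seed = 1, fps = 5) {
  if (!inherits(boundaries, "segment_boundaries")) {
    input_error("`boundaries` must be segment_boundaries")
  }
  segs <- if (boundaries$mode == "three") SEGMENTS3 else SEGMENTS5
  latents <- as.integer(latents)
  if (length(latents) != length(segs) || anyNA(latents) ||
      any(latents < 1 | latents > 4)) {
    input_error(sprintf("`latents` must be %d grades in 1..4", length(segs)))
  }
  if (!is_count(n_frames)) input_error("`n_frames` must be a positive integer")
  if (!is.numeric(noise) || noise < 0) input_error("`noise` must be >= 0")
  edges <- c(0L, boundaries$boundaries, as.integer(n_frames))
  sizes <- diff(edges)
  if (any(sizes <= 0L)) {
    data_error(paste("empty colon segment:",
                     paste(segs[sizes <= 0L], collapse = ", ")))
  }
  ratings <- with_seed(seed, {
    unlist(lapply(seq_along(segs), function(k) {
      rtrunc_ratings(sizes[k], latents[k] + 0.5, noise)
    }))
  })
  out <- data.frame(
    frame_index = seq_len(n_frames) - 1L,
    timestamp_s = (seq_len(n_frames) - 1L) / fps,
    clean_fraction = (ratings - 1) / 4,
    rating = ratings,
    segment = rep(segs, sizes)
  )
  attr(out, "latents") <- stats::setNames(latents, segs)
  out
}

#' Simulate a human reader report from latent segment qualities
#'
#' Each reported grade is drawn from the confusion-matrix row of its latent
#' grade: `P(reported = j | latent = i) = confusion[i, j]`. An identity matrix
#' reproduces the latents exactly; uniform rows make the reader independent of
#' the truth.
#'
#' @param latents integer latent grades in 1-4 for the five segments (cecum,
#'   right-sided colon, transverse, left-sided colon, rectum).
#' @param confusion 4 x 4 row-stochastic matrix.
#' @param seed RNG seed.
#' @param video_id identifier carried into the report.
#' @param boundaries optional [segment_boundaries()] recorded in the report.
#' @return list of class `reader_report`: `video_id`, `grades` (named,
#'   five), `boundaries`.
#' @export
generate_reader_report <- function(latents, confusion = diag(4), seed = 1,
                                   video_id = "vid0001", boundaries = NULL) {
  latents <- as.integer(latents)
  if (length(latents) != 5L || anyNA(latents) || any(latents < 1 | latents > 4)) {
    input_error("`latents` must be five grades in 1..4")
  }
  check_confusion(confusion)
  grades <- with_seed(seed, draw_reader_grades(latents, confusion))
  structure(
    list(video_id = video_id,
         grades = stats::setNames(grades, SEGMENTS5),
         boundaries = boundaries),
    class = "reader_report"
  )
}

check_confusion <- function(confusion) {
  if (!is.matrix(confusion) || !all(dim(confusion) == c(4L, 4L)) ||
      anyNA(confusion) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-8)) {
    config_error("`confusion` must be a 4 x 4 row-stochastic matrix")
  }
}

draw_reader_grades <- function(latents, confusion) {
  vapply(latents, function(g) {
    sample.int(4L, 1L, prob = confusion[g, ])
  }, integer(1))
}

#' Cohort simulation configuration
#'
#' Describes a synthetic study cohort. Each video gets a latent whole-video
#' cleansing quality drawn from `latent_dist`; each of its five segments takes
#' that grade shifted by -1/0/+1 with probabilities
#' `(segment_drift/2, 1 - segment_drift, segment_drift/2)` (clamped to 1-4),
#' so segment qualities are correlated within a video as they are in real
#' preparations. Frame ratings then follow [generate_rating_stream()] and the
#' paired reader report follows [generate_reader_report()].
#'
#' @param n_videos number of videos.
#' @param frames_range integer length-2, inclusive range of frames per video.
#' @param latent_dist probabilities over latent video grades 1-4.
#' @param segment_drift probability that a segment deviates (by one grade)
#'   from the video latent; 0 makes all five segments share the video grade.
#' @param noise within-segment rating spread (standard deviation).
#' @param confusion 4 x 4 reader confusion matrix.
#' @param fps frames per second for timestamps.
#' @param length_shape gamma shape controlling segment-length variability
#'   (larger = more even segments).
#' @return list of class `cohort_config`.
#' @seealso [study_preset()], [generate_cohort()]
#' @export
cohort_config <- function(n_videos = 100,
                          frames_range = c(200, 400),
                          latent_dist = c(0.10, 0.25, 0.40, 0.25),
                          segment_drift = 0.2,
                          noise = 0.5,
                          confusion = diag(4),
                          fps = 5,
                          length_shape = 20) {
  if (!is_count(n_videos)) config_error("`n_videos` must be a positive integer")
  if (length(frames_range) != 2L || !all(vapply(frames_range, is_count, logical(1))) ||
      frames_range[1] > frames_range[2] || frames_range[1] < 5) {
    config_error("`frames_range` must be an increasing pair of counts >= 5")
  }
  if (length(latent_dist) != 4L || any(latent_dist < 0) ||
      abs(sum(latent_dist) - 1) > 1e-8) {
    config_error("`latent_dist` must be 4 probabilities summing to 1")
  }
  if (!is.numeric(segment_drift) || segment_drift < 0 || segment_drift > 1) {
    config_error("`segment_drift` must be in [0, 1]")
  }
  if (!is.numeric(noise) || noise < 0) config_error("`noise` must be >= 0")
  check_confusion(confusion)
  structure(
    list(n_videos = as.integer(n_videos),
         frames_range = as.integer(frames_range),
         latent_dist = latent_dist, segment_drift = segment_drift,
         noise = noise, confusion = confusion, fps = fps,
         length_shape = length_shape),
    class = "cohort_config"
  )
}

#' Study-like cohort preset
#'
#' A [cohort_config()] calibrated so that a cohort of 842 videos reproduces
#' the overall 2-point marginals of the motivating interobserver study:
#' roughly 26% of videos reader-nonacceptable and 6% algorithm-nonacceptable
#' under mean-based grading.
#'
#' @param n_videos cohort size (study size by default).
#' @return a `cohort_config`.
#' @export
study_preset <- function(n_videos = 842) {
  confusion <- matrix(c(
    0.750, 0.200, 0.040, 0.010,
    0.080, 0.740, 0.150, 0.030,
    0.015, 0.130, 0.685, 0.170,
    0.010, 0.040, 0.220, 0.730
  ), 4, 4, byrow = TRUE)
  cohort_config(
    n_videos = n_videos,
    frames_range = c(200, 400),
    latent_dist = c(0.06, 0.29, 0.40, 0.25),
    segment_drift = 0.20,
    noise = 0.5,
    confusion = confusion
  )
}

draw_segment_latents <- function(video_latent, drift) {
  delta <- sample(c(-1L, 0L, 1L), 5L, replace = TRUE,
                  prob = c(drift / 2, 1 - drift, drift / 2))
  pmax(1L, pmin(4L, video_latent + delta))
}

# Segment lengths: gamma-distributed proportions, every segment >= 1 frame.
draw_segment_lengths <- function(n_frames, shape) {
  g <- stats::rgamma(5, shape = shape)
  len <- floor(n_frames * g / sum(g))
  len <- pmax(len, 1L)
  len[5] <- n_frames - sum(len[1:4])
  while (len[5] < 1L) { # borrow from the largest segment if rounding overshot
    i <- which.max(len[1:4])
    len[i] <- len[i] - 1L
    len[5] <- len[5] + 1L
  }
  as.integer(len)
}

#' Generate a full synthetic study cohort
#'
#' Produces, for every video, a per-frame rating stream with five-segment
#' structure, a paired human reader report, and the latent ground truth. A
#' pure function of `(config, seed)`: the same pair always yields identical
#' output (and byte-identical files when `dir` is given).
#'
#' @param config a [cohort_config()].
#' @param seed master RNG seed.
#' @param dir optional output directory; writes `frame_scores.csv`,
#'   `reader_reports.csv` and `ground_truth.json` (plus PNG frames under
#'   `frames/<video_id>/` when `write_frames = TRUE`).
#' @param write_frames also render each frame as a PNG image (slow; intended
#'   for small image-mode cohorts only).
#' @param frame_size pixel side length of rendered frames.
#' @return list with `frame_scores` (one data.frame over all videos),
#'   `reader_reports` (data.frame), `ground_truth` (per-video list), `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1, dir = NULL,
                            write_frames = FALSE, frame_size = 32) {
  stopifnot(inherits(config, "cohort_config"))
  res <- with_seed(seed, {
    scores <- vector("list", config$n_videos)
    reports <- vector("list", config$n_videos)
    truth <- vector("list", config$n_videos)
    for (i in seq_len(config$n_videos)) {
      vid <- sprintf("vid%04d", i)
      span <- config$frames_range[1]:config$frames_range[2]
      n_frames <- span[sample.int(length(span), 1L)]
      lens <- draw_segment_lengths(n_frames, config$length_shape)
      bounds <- cumsum(lens)[1:4]
      video_latent <- sample.int(4L, 1L, prob = config$latent_dist)
      latents <- draw_segment_latents(video_latent, config$segment_drift)
      ratings <- unlist(lapply(1:5, function(k) {
        rtrunc_ratings(lens[k], latents[k] + 0.5, config$noise)
      }))
      reported <- draw_reader_grades(latents, config$confusion)
      scores[[i]] <- data.frame(
        video_id = vid,
        frame_index = seq_len(n_frames) - 1L,
        timestamp_s = (seq_len(n_frames) - 1L) / config$fps,
        clean_fraction = (ratings - 1) / 4,
        rating = ratings,
        segment = rep(SEGMENTS5, lens)
      )
      reports[[i]] <- data.frame(
        video_id = vid,
        grade_cecum = reported[1], grade_right = reported[2],
        grade_transverse = reported[3], grade_left = reported[4],
        grade_rectum = reported[5],
        b_cecum_end = bounds[1], b_hepatic = bounds[2],
        b_splenic = bounds[3], b_rectosigmoid = bounds[4],
        n_frames = n_frames
      )
      truth[[i]] <- list(video_id = vid, video_latent = video_latent,
                         segment_latents = stats::setNames(latents, SEGMENTS5),
                         boundaries = bounds, n_frames = n_frames)
    }
    list(frame_scores = do.call(rbind, scores),
         reader_reports = do.call(rbind, reports),
         ground_truth = truth)
  })
  res$config <- config
  res$seed <- seed
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_frame_scores(res$frame_scores, file.path(dir, "frame_scores.csv"))
    write_reader_reports(res$reader_reports, file.path(dir, "reader_reports.csv"))
    jsonlite::write_json(res$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (write_frames) {
      for (i in seq_len(config$n_videos)) {
        vid <- res$ground_truth[[i]]$video_id
        fdir <- file.path(dir, "frames", vid)
        dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
        rows <- res$frame_scores[res$frame_scores$video_id == vid, ]
        for (j in seq_len(nrow(rows))) {
          fr <- generate_frame_image(1 - rows$clean_fraction[j],
                                     size = frame_size,
                                     seed = (seed + i * 100003 + j) %% .Machine$integer.max)
          png::writePNG(fr$image,
                        file.path(fdir, sprintf("frame_%05d.png", j - 1L)))
        }
      }
    }
  }
  res
}
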