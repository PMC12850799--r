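# Per-frame cleanliness scoring: pixel classification, clean fraction,
# continuous rating.

#' Pixel classifier configuration
#'
#' Settings for the rule-based clean/dirty pixel classifier. A pixel is
#' labelled *dirty* when its hue falls inside `hue_band` (degrees, possibly
#' wrapping through 0/360) **and** its saturation and value (HSV) are at least
#' `saturation_min` and `value_min`. The defaults target the yellow/brown hues
#' of fecal residue at sufficient saturation and brightness; clean pink/red
#' mucosa falls outside the band. All thresholds are configurable because
#' lighting and capsule hardware vary.
#'
#' @param hue_band numeric length-2, hue interval in degrees, each in
#'   `[0, 360)`. If the first bound exceeds the second the band wraps through
#'   zero.
#' @param saturation_min minimum HSV saturation in `[0, 1]` for a dirty pixel.
#' @param value_min minimum HSV value (brightness) in `[0, 1]` for a dirty
#'   pixel; suppresses dark shadow pixels.
#' @return An object of class `classifier_config`.
#' @examples
#' classifier_config()
#' classifier_config(hue_band = c(15, 80), saturation_min = 0.25)
#' @export
classifier_config <- function(hue_band = c(20, 70),
                              saturation_min = 0.35,
                              value_min = 0.15) {
  if (!is.numeric(hue_band) || length(hue_band) != 2L || anyNA(hue_band)) {
    config_error("`hue_band` must be two hue bounds in degrees")
  }
  hue_band <- hue_band %% 360
  for (nm in c("saturation_min", "value_min")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      config_error(sprintf("`%s` must be a single value in [0, 1]", nm))
    }
  }
  structure(
    list(hue_band = hue_band, saturation_min = saturation_min,
         value_min = value_min),
    class = "classifier_config"
  )
}

#' Classify frame pixels as clean or dirty
#'
#' Applies the HSV-threshold rule of [classifier_config()] to every pixel of
#' an RGB frame. The classification is deterministic: the same frame and
#' configuration always produce the identical mask.
#'
#' @param frame numeric array `height x width x 3` (RGB). Values may be on
#'   `[0, 1]` (as returned by [png::readPNG()]) or `[0, 255]`. A fourth alpha
#'   channel, if present, is ignored.
#' @param config a [classifier_config()].
#' @return A `pixel_mask`: a logical `height x width` matrix, `TRUE` = dirty.
#' @seealso [clean_fraction()], [generate_frame_image()]
#' @export
classify_pixels <- function(frame, config = classifier_config()) {
  if (!inherits(config, "classifier_config")) {
    config_error("`config` must be a classifier_config")
  }
  if (!is.array(frame) || length(dim(frame)) != 3L) {
    input_error("`frame` must be a height x width x channel array")
  }
  d <- dim(frame)
  if (d[1] < 1 || d[2] < 1) input_error("`frame` has no pixels")
  if (d[3] == 4L) frame <- frame[, , 1:3, drop = FALSE]
  if (dim(frame)[3] != 3L) input_error("`frame` must have 3 (RGB) channels")
  if (!is.numeric(frame) || anyNA(frame)) input_error("`frame` must be numeric without NA")
  if (max(frame) > 1) frame <- frame / 255

  rgb <- matrix(aperm(frame, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1, ] * 360
  s <- hsv[2, ]
  v <- hsv[3, ]

  lo <- config$hue_band[1]
  hi <- config$hue_band[2]
  in_band <- if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
  dirty <- in_band & s >= config$saturation_min & v >= config$value_min
  structure(matrix(dirty, nrow = d[1], ncol = d[2]),
            class = c("pixel_mask", "matrix"))
}

#' Clean-pixel fraction of a mask
#'
#' The share of pixels labelled clean: `clean / (clean + dirty)`. Bounded in
#' `[0, 1]` and defined even when no pixel is dirty, which makes it stable
#' under the downstream percentile summaries. The literal clean-to-dirty
#' quotient is available as [clean_dirty_ratio()].
#'
#' @param mask a `pixel_mask` from [classify_pixels()] (or any logical matrix
#'   with `TRUE` = dirty).
#' @return numeric in `[0, 1]`.
#' @export
clean_fraction <- function(mask) {
  if (!is.logical(mask) || length(mask) == 0L) {
    input_error("`mask` must be a non-empty logical pixel mask")
  }
  1 - mean(mask)
}

#' Clean-to-dirty pixel quotient
#'
#' The raw quotient `n_clean / n_dirty`; `Inf` for a fully clean frame. A
#' derived convenience value — grading works on [clean_fraction()].
#'
#' @inheritParams clean_fraction
#' @return numeric in `[0, Inf]`.
#' @export
clean_dirty_ratio <- function(mask) {
  if (!is.logical(mask) || length(mask) == 0L) {
    input_error("`mask` must be a non-empty logical pixel mask")
  }
  n_dirty <- sum(mask)
  if (n_dirty == 0L) Inf else (length(mask) - n_dirty) / n_dirty
}

#' Map a clean fraction to the continuous cleanliness rating
#'
#' Affine map `1 + 4 * f` from the clean-pixel fraction onto the continuous
#' grade scale `[1, 5)`, clamped just below 5 so that flooring a rating always
#' yields a valid 4-point grade (poor/fair/good/excellent at clean fractions
#' <25%, 25-50%, 50-75%, >=75%). Strictly increasing on `[0, 1)` before the
#' clamp.
#'
#' @param f numeric vector of clean fractions in `[0, 1]`.
#' @param eps clamp margin below 5; ratings never reach `5 - eps + ...` = 5.
#' @return numeric vector of ratings in `[1, 5)`.
#' @export
fraction_to_rating <- function(f, eps = 1e-6) {
  if (!is.numeric(f) || anyNA(f) || any(f < 0 | f > 1)) {
    input_error("`f` must be numeric in [0, 1]")
  }
  pmin(1 + 4 * f, 5 - eps)
}

#' Score a directory of frame images
#'
#' Reads PNG frames (lexicographic file order = frame order), classifies each
#' with [classify_pixels()] and returns per-frame clean fractions and ratings.
#'
#' @param path directory containing `.png` frames, or a character vector of
#'   PNG file paths in frame order.
#' @param config a [classifier_config()].
#' @param timestamps optional numeric vector of per-frame timestamps in
#'   seconds (recycled checks: must match the frame count).
#' @return data.frame with columns `frame_index` (0-based), `timestamp_s`,
#'   `clean_fraction`, `rating`.
#' @export
score_frames <- function(path, config = classifier_config(), timestamps = NULL) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                    ignore.case = TRUE))
  } else {
    path
  }
  if (length(files) == 0L) input_error("no PNG frames found")
  missing <- files[!file.exists(files)]
  if (length(missing)) input_error(paste("missing frame file:", missing[1]))
  if (!is.null(timestamps) && length(timestamps) != length(files)) {
    input_error("`timestamps` length must equal the number of frames")
  }
  cf <- vapply(files, function(fp) {
    clean_fraction(classify_pixels(png::readPNG(fp), config))
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(
    frame_index = seq_along(files) - 1L,
    timestamp_s = if (is.null(timestamps)) NA_real_ else as.numeric(timestamps),
    clean_fraction = cf,
    rating = fraction_to_rating(cf)
  )
}

#' Write / read per-frame score tables
#'
#' CSV schema: `video_id, frame_index, timestamp_s, clean_fraction, rating`,
#' numeric columns written with 6 decimal places.
#'
#' @param scores data.frame with at least `video_id`, `frame_index`, `rating`;
#'   `timestamp_s` and `clean_fraction` are filled with `NA` if absent.
#' @param path CSV file path.
#' @return `write_frame_scores()` returns `path` invisibly;
#'   `read_frame_scores()` returns the data.frame.
#' @export
write_frame_scores <- function(scores, path) {
  need <- c("video_id", "frame_index", "rating")
  if (!all(need %in% names(scores))) {
    input_error(paste("frame scores need columns:", paste(need, collapse = ", ")))
  }
  out <- data.frame(
    video_id = scores$video_id,
    frame_index = as.integer(scores$frame_index),
    timestamp_s = sprintf("%.6f", scores$timestamp_s %||% NA_real_),
    clean_fraction = sprintf("%.6f", scores$clean_fraction %||% NA_real_),
    rating = sprintf("%.6f", scores$rating)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_scores
#' @export
read_frame_scores <- function(path) {
  if (!file.exists(path)) input_error(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("timestamp_s", "clean_fraction", "rating")) {
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$frame_index <- as.integer(df$frame_index)
  df
}
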