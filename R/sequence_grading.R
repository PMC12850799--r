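# Sequence-level grading: distribution summaries of per-frame ratings and
# their mapping to the 4-point Leighton-Rex and 2-point acceptability scales.

SUMMARY_STATS <- c("mean", "median", "q1", "q3", "p2", "p98")

GRADE_LABELS <- c("poor", "fair", "good", "excellent")
BINARY_LABELS <- c("nonacceptable", "acceptable")

#' Labels for grade codes
#'
#' @param g integer grades 1-4 (`grade_label`) or binary codes 1-2
#'   (`binary_label`, 1 = nonacceptable, 2 = acceptable).
#' @return character vector of labels.
#' @export
grade_label <- function(g) GRADE_LABELS[as.integer(g)]

#' @rdname grade_label
#' @export
binary_label <- function(g) BINARY_LABELS[as.integer(g)]

#' Summarize a stream of frame-cleanliness ratings
#'
#' Computes the six distribution statistics used for sequence grading: mean,
#' median, lower and upper quartiles, and the 2nd and 98th percentiles. The
#' percentile convention is linear interpolation between closest ranks
#' (`stats::quantile` type 7) by default, switchable to nearest rank (type 1);
#' the choice only matters for short streams.
#'
#' @param ratings non-empty numeric vector of per-frame ratings.
#' @param percentile_method `"linear"` (interpolated) or `"nearest"`
#'   (nearest rank).
#' @return A `cleanliness_summary`: list with `n_frames`, `mean`, `median`,
#'   `q1`, `q3`, `p2`, `p98`, `percentile_method`.
#' @examples
#' summarize_ratings(c(1.2, 3.4, 4.1, 2.2))
#' @export
summarize_ratings <- function(ratings, percentile_method = c("linear", "nearest")) {
  percentile_method <- match.arg(percentile_method)
  if (length(ratings) == 0L) input_error("rating stream is empty")
  if (!is.numeric(ratings) || anyNA(ratings) || any(!is.finite(ratings))) {
    input_error("ratings must be finite numeric values")
  }
  type <- if (percentile_method == "linear") 7 else 1
  q <- unname(stats::quantile(ratings, c(0.02, 0.25, 0.5, 0.75, 0.98),
                              type = type, names = FALSE))
  structure(
    list(n_frames = length(ratings), mean = mean(ratings), median = q[3],
         q1 = q[2], q3 = q[4], p2 = q[1], p98 = q[5],
         percentile_method = percentile_method),
    class = "cleanliness_summary"
  )
}

#' @export
print.cleanliness_summary <- function(x, ...) {
  cat(sprintf(
    "Cleanliness summary (%d frames, %s percentiles)\n  mean %.3f  median %.3f  q1 %.3f  q3 %.3f  p2 %.3f  p98 %.3f\n",
    x$n_frames, x$percentile_method, x$mean, x$median, x$q1, x$q3, x$p2, x$p98
  ))
  invisible(x)
}

#' Map a summary statistic to the 4-point Leighton-Rex grade
#'
#' Rounds the continuous value down to the nearest integer (exact integers map
#' to themselves) and clamps into `{1, 2, 3, 4}`. Values below 1, which a
#' rule-based classifier can emit at the scale floor, clamp to 1 (poor) with a
#' warning rather than an error.
#'
#' @param x numeric vector of summary values on the `[1, 5)` rating scale.
#' @return integer vector of grades in 1-4 (1 = poor ... 4 = excellent).
#' @export
rating_to_grade <- function(x) {
  if (!is.numeric(x) || anyNA(x)) input_error("grade input must be numeric without NA")
  if (any(x < 1)) {
    warning("summary value below 1 clamped to grade 1 (poor)", call. = FALSE)
  }
  as.integer(pmax(1, pmin(4, floor(x))))
}

#' Collapse a 4-point grade to the 2-point acceptability scale
#'
#' Poor is nonacceptable; fair, good and excellent are acceptable.
#'
#' @param g integer vector of grades in 1-4.
#' @return integer vector: 1 = nonacceptable, 2 = acceptable.
#' @export
grade_to_binary <- function(g) {
  g <- as.integer(g)
  if (anyNA(g) || any(g < 1 | g > 4)) input_error("grades must be integers in 1..4")
  ifelse(g == 1L, 1L, 2L)
}

#' Grade a rating stream by one summary statistic
#'
#' Composition of [summarize_ratings()], [rating_to_grade()] and
#' [grade_to_binary()] for a chosen statistic.
#'
#' @inheritParams summarize_ratings
#' @param statistic one of `"mean"`, `"median"`, `"q1"`, `"q3"`, `"p2"`,
#'   `"p98"`.
#' @return list with `value` (the statistic), `grade` (1-4) and `binary`
#'   (1 = nonacceptable, 2 = acceptable).
#' @export
grade_scope <- function(ratings, statistic,
                        percentile_method = c("linear", "nearest")) {
  if (!is.character(statistic) || length(statistic) != 1L ||
      !statistic %in% SUMMARY_STATS) {
    config_error(paste("unknown statistic; expected one of:",
                       paste(SUMMARY_STATS, collapse = ", ")))
  }
  s <- summarize_ratings(ratings, percentile_method)
  x <- s[[statistic]]
  g <- rating_to_grade(x)
  list(value = x, grade = g, binary = grade_to_binary(g))
}

# All six statistics of a stream graded at once; rows = statistic.
grade_all_stats <- function(ratings, percentile_method = "linear") {
  s <- summarize_ratings(ratings, percentile_method)
  vals <- unlist(s[SUMMARY_STATS])
  g <- suppressWarnings(rating_to_grade(vals))
  data.frame(statistic = SUMMARY_STATS, value = unname(vals),
             grade = g, binary = grade_to_binary(g), row.names = NULL)
}
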