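# Colon segmentation from reader-reported flexure positions, 5-to-3 segment
# merging of reader grades, and overall-acceptability rules.

SEGMENTS3 <- c("right", "transverse", "left")
SEGMENTS5 <- c("cecum", "right", "transverse", "left", "rectum")

#' Segment boundaries of a colon frame stream
#'
#' Boundaries are 0-based frame indices splitting the stream into half-open
#' intervals `[start, end)`. Three-segment mode takes the hepatic and splenic
#' flexures; five-segment mode additionally takes the cecum end and the
#' rectosigmoid junction. Timestamps in seconds can be converted with
#' [timestamps_to_indices()].
#'
#' @param boundaries strictly increasing integer frame indices: length 2 for
#'   `mode = "three"` (hepatic flexure, splenic flexure), length 4 for
#'   `mode = "five"` (cecum end, hepatic flexure, splenic flexure,
#'   rectosigmoid junction).
#' @param mode `"three"` or `"five"`.
#' @param n_frames optional total frame count; boundaries must lie in
#'   `[0, n_frames]`.
#' @return A `segment_boundaries` object.
#' @export
segment_boundaries <- function(boundaries, mode = c("three", "five"),
                               n_frames = NULL) {
  mode <- match.arg(mode)
  want <- if (mode == "three") 2L else 4L
  if (!is.numeric(boundaries) || length(boundaries) != want ||
      anyNA(boundaries) || any(boundaries != floor(boundaries))) {
    input_error(sprintf("mode '%s' needs %d integer boundaries", mode, want))
  }
  boundaries <- as.integer(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE)) {
    input_error("boundaries must be strictly increasing")
  }
  if (any(boundaries < 0)) input_error("boundaries must be >= 0")
  if (!is.null(n_frames) && any(boundaries > n_frames)) {
    input_error("boundaries exceed the frame count")
  }
  structure(list(mode = mode, boundaries = boundaries, n_frames = n_frames),
            class = "segment_boundaries")
}

#' Convert boundary timestamps to frame indices
#'
#' Maps each boundary timestamp to the index of the first frame at or after
#' it, using the per-frame timestamp table.
#'
#' @param ts numeric boundary timestamps in seconds.
#' @param frame_timestamps numeric vector of per-frame timestamps (frame order).
#' @return integer frame indices (0-based).
#' @export
timestamps_to_indices <- function(ts, frame_timestamps) {
  if (is.unsorted(frame_timestamps)) input_error("frame timestamps must be nondecreasing")
  vapply(ts, function(t) {
    i <- which(frame_timestamps >= t)
    if (length(i) == 0L) length(frame_timestamps) else i[1] - 1L
  }, integer(1))
}

#' Partition a rating stream into colon segments
#'
#' Half-open partition: frame `i` (0-based) belongs to segment `k` iff
#' `boundary[k-1] <= i < boundary[k]`, with implicit outer boundaries 0 and
#' `n_frames`. Segments are disjoint and cover the stream, so the per-segment
#' streams concatenate back to the input.
#'
#' @param ratings numeric vector of per-frame ratings in frame order.
#' @param b a [segment_boundaries()] object.
#' @return Named list of rating vectors: `right`, `transverse`, `left`
#'   (three-mode) or `cecum`, `right`, `transverse`, `left`, `rectum`
#'   (five-mode).
#' @export
assign_segments <- function(ratings, b) {
  if (!inherits(b, "segment_boundaries")) input_error("`b` must be segment_boundaries")
  n <- length(ratings)
  if (n == 0L) input_error("rating stream is empty")
  if (any(b$boundaries > n)) input_error("boundaries exceed the frame count")
  edges <- c(0L, b$boundaries, n)
  names <- if (b$mode == "three") SEGMENTS3 else SEGMENTS5
  sizes <- diff(edges)
  if (any(sizes == 0L)) {
    data_error(paste("empty colon segment:",
                     paste(names[sizes == 0L], collapse = ", ")))
  }
  out <- lapply(seq_along(names), function(k) {
    ratings[(edges[k] + 1L):edges[k + 1L]]
  })
  names(out) <- names
  out
}

#' Merge reader 5-segment grades to the 3-segment division
#'
#' The cecum and right-sided colon grades are combined as the lower of the
#' two; likewise the left-sided colon and rectum. The transverse colon is
#' unchanged. Matches the convention used when reader reports carry five
#' segments but the flexure timestamps only support a three-segment split.
#'
#' @param grades integer vector of five grades in 1-4, ordered (cecum,
#'   right-sided colon, transverse colon, left-sided colon, rectum).
#' @return named integer vector of three grades (right, transverse, left).
#' @export
merge_reader_5_to_3 <- function(grades) {
  grades <- as.integer(grades)
  if (length(grades) != 5L || anyNA(grades) || any(grades < 1 | grades > 4)) {
    input_error("`grades` must be five grades in 1..4")
  }
  c(right = min(grades[1], grades[2]),
    transverse = grades[3],
    left = min(grades[4], grades[5]))
}

#' Overall acceptability from segment acceptabilities
#'
#' The whole examination is acceptable only if every segment is acceptable.
#'
#' @param segment_binaries integer vector of binary codes (1 = nonacceptable,
#'   2 = acceptable), one per segment.
#' @return single binary code.
#' @export
overall_binary <- function(segment_binaries) {
  b <- as.integer(segment_binaries)
  if (length(b) == 0L) input_error("no segment assessments given")
  if (anyNA(b) || any(!b %in% 1:2)) input_error("binary codes must be 1 or 2")
  if (any(b == 1L)) 1L else 2L
}

#' Overall 4-point reader grade from segment grades
#'
#' The minimum of the per-segment grades — a whole-colon grade consistent with
#' the all-segments-acceptable rule: its binary collapse always equals
#' [overall_binary()] of the per-segment binary collapses.
#'
#' @param grades integer vector of segment grades in 1-4.
#' @return single integer grade.
#' @export
overall_reader_grade <- function(grades) {
  g <- as.integer(grades)
  if (length(g) == 0L) input_error("no segment grades given")
  if (anyNA(g) || any(g < 1 | g > 4)) input_error("grades must be integers in 1..4")
  min(g)
}

#' Read reader reports from CSV or JSON
#'
#' Expected columns/fields: `video_id`, the five segment grades
#' `grade_cecum`, `grade_right`, `grade_transverse`, `grade_left`,
#' `grade_rectum` (integers 1-4), and boundary frame indices `b_cecum_end`,
#' `b_hepatic`, `b_splenic`, `b_rectosigmoid` (the outer two may be `NA` when
#' only the flexures were reported).
#'
#' @param path a `.csv` or `.json` file.
#' @return data.frame of reader reports.
#' @export
read_reader_reports <- function(path) {
  if (!file.exists(path)) input_error(paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_reader_reports(df)
  df
}

#' @rdname read_reader_reports
#' @param reports data.frame of reader reports.
#' @export
write_reader_reports <- function(reports, path) {
  validate_reader_reports(reports)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(reports, path, dataframe = "rows", digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    utils::write.csv(reports, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

validate_reader_reports <- function(df) {
  grade_cols <- paste0("grade_", SEGMENTS5)
  need <- c("video_id", grade_cols)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    data_error(paste("reader reports missing columns:",
                     paste(missing, collapse = ", ")))
  }
  for (col in grade_cols) {
    g <- df[[col]]
    bad <- which(is.na(g) | g < 1 | g > 4 | g != floor(g))
    if (length(bad)) {
      data_error(sprintf("invalid grade in %s, record %d (video_id %s)",
                         col, bad[1], df$video_id[bad[1]]))
    }
  }
  invisible(df)
}
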