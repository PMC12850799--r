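# End-to-end orchestration: grade per-video streams against reader reports,
# run every agreement comparison, render and serialize the report.

#' Published total-colon contingency tables
#'
#' The 2-point total-colon cross-tabulations (algorithm rows, reader columns;
#' categories nonacceptable, acceptable) printed by the motivating 842-video
#' interobserver study, for mean-based and median-based algorithm grading.
#' Useful as reference inputs: re-running the agreement analysis on them
#' reproduces the study's published kappa values (.10 and .12) and percent
#' agreements (73.9% and 73.8%).
#'
#' @return named list of two `contingency_table`s: `mean` and `median`.
#' @examples
#' cohen_kappa(study_contingency_tables()$mean)
#' @export
study_contingency_tables <- function() {
  dn <- list(algorithm = BINARY_LABELS, reader = BINARY_LABELS)
  list(
    mean = as_contingency(matrix(c(26, 24, 196, 596), 2, 2,
                                 byrow = TRUE, dimnames = dn)),
    median = as_contingency(matrix(c(30, 29, 192, 591), 2, 2,
                                   byrow = TRUE, dimnames = dn))
  )
}

# Per-video grading: AIA grades (all statistics, total + per-segment pooled
# streams) paired with the reader's overall and merged segment grades.
grade_video <- function(ratings, report_row, statistics, percentile_method,
                        segment_mode) {
  grades5 <- as.integer(unlist(report_row[paste0("grade_", SEGMENTS5)]))
  n <- length(ratings)

  if (segment_mode == "three") {
    b <- segment_boundaries(c(report_row$b_hepatic, report_row$b_splenic),
                            mode = "three", n_frames = n)
    reader_seg <- merge_reader_5_to_3(grades5)
  } else {
    bs <- as.integer(unlist(report_row[c("b_cecum_end", "b_hepatic", "b_splenic",
                                  "b_rectosigmoid")]))
    if (anyNA(bs)) data_error(paste("five-segment boundaries missing for",
                                    report_row$video_id))
    b <- segment_boundaries(bs, mode = "five", n_frames = n)
    reader_seg <- stats::setNames(grades5, SEGMENTS5)
  }
  reader_overall <- overall_reader_grade(grades5)

  rows <- list()
  total <- grade_all_stats(ratings, percentile_method)
  total <- total[total$statistic %in% statistics, ]
  rows[[1]] <- data.frame(
    video_id = report_row$video_id, scope = "total",
    statistic = total$statistic, aia_grade = total$grade,
    aia_binary = total$binary, reader_grade = reader_overall,
    reader_binary = grade_to_binary(reader_overall)
  )
  segs <- assign_segments(ratings, b)
  for (sg in names(segs)) {
    g <- grade_all_stats(segs[[sg]], percentile_method)
    g <- g[g$statistic %in% statistics, ]
    rows[[length(rows) + 1L]] <- data.frame(
      video_id = report_row$video_id, scope = sg,
      statistic = g$statistic, aia_grade = g$grade, aia_binary = g$binary,
      reader_grade = unname(reader_seg[sg]),
      reader_binary = grade_to_binary(reader_seg[sg])
    )
  }
  do.call(rbind, rows)
}

#' Run the full agreement study
#'
#' For every video, grades the whole-colon stream and each flexure-delimited
#' segment with the requested summary statistics, pairs the results with the
#' human reader's overall (minimum over segments) and merged segment grades,
#' and computes percent agreement, Cohen's kappa (2-point scale) and weighted
#' kappa (4-point scale) for each scope x statistic. Videos whose boundaries
#' produce an empty segment are dropped from the segmental comparisons (with a
#' logged count); the whole-colon comparison keeps every parseable video.
#' Deterministic: identical inputs yield an identical report.
#'
#' @param frame_scores data.frame with `video_id`, `frame_index`, `rating`
#'   (from [score_frames()]/[generate_cohort()] or [read_frame_scores()]).
#' @param reader_reports data.frame of reader reports (see
#'   [read_reader_reports()]).
#' @param statistics summary statistics to evaluate.
#' @param scheme weighting scheme for the 4-point weighted kappa.
#' @param percentile_method percentile convention, see [summarize_ratings()].
#' @param segment_mode `"three"` (flexure split, reader grades min-merged) or
#'   `"five"` (requires all four boundaries).
#' @return An `agreement_report`: list with `meta` (run settings and
#'   exclusion counts), `pairs` (the long per-video grade table) and
#'   `comparisons` (one entry per scope x statistic x scale with the
#'   contingency counts and kappa results).
#' @export
run_study <- function(frame_scores, reader_reports,
                      statistics = SUMMARY_STATS,
                      scheme = c("linear", "quadratic"),
                      percentile_method = c("linear", "nearest"),
                      segment_mode = c("three", "five")) {
  scheme <- match.arg(scheme)
  percentile_method <- match.arg(percentile_method)
  segment_mode <- match.arg(segment_mode)
  bad <- setdiff(statistics, SUMMARY_STATS)
  if (length(bad)) config_error(paste("unknown statistic:", paste(bad, collapse = ", ")))
  validate_reader_reports(reader_reports)
  need <- c("video_id", "frame_index", "rating")
  if (!all(need %in% names(frame_scores))) {
    data_error(paste("frame scores need columns:", paste(need, collapse = ", ")))
  }

  ids <- unique(reader_reports$video_id)
  ids <- ids[ids %in% unique(frame_scores$video_id)]
  if (length(ids) == 0L) data_error("no videos shared by frame scores and reader reports")

  score_split <- split(frame_scores[c("frame_index", "rating")],
                       frame_scores$video_id)
  pair_rows <- vector("list", length(ids))
  dropped <- character(0)
  for (i in seq_along(ids)) {
    vid <- ids[i]
    sub <- score_split[[vid]]
    ratings <- sub$rating[order(sub$frame_index)]
    row <- reader_reports[reader_reports$video_id == vid, , drop = FALSE][1, ]
    pair_rows[[i]] <- tryCatch(
      grade_video(ratings, row, statistics, percentile_method, segment_mode),
      ccecleanse_data_error = function(e) {
        dropped <<- c(dropped, vid)
        # keep the whole-colon comparison for this video
        g <- grade_all_stats(ratings, percentile_method)
        g <- g[g$statistic %in% statistics, ]
        ro <- overall_reader_grade(as.integer(unlist(row[paste0("grade_", SEGMENTS5)])))
        data.frame(video_id = vid, scope = "total", statistic = g$statistic,
                   aia_grade = g$grade, aia_binary = g$binary,
                   reader_grade = ro, reader_binary = grade_to_binary(ro))
      }
    )
  }
  pairs <- do.call(rbind, pair_rows)
  seg_names <- if (segment_mode == "three") SEGMENTS3 else SEGMENTS5

  comparisons <- list()
  for (stat in statistics) {
    for (scope in c("total", "segmental", seg_names)) {
      sub <- if (scope == "segmental") {
        pairs[pairs$scope %in% seg_names & pairs$statistic == stat, ]
      } else {
        pairs[pairs$scope == scope & pairs$statistic == stat, ]
      }
      if (nrow(sub) == 0L) next
      for (scale in c("binary", "fourpoint")) {
        if (scale == "binary") {
          t <- build_contingency(sub$aia_binary, sub$reader_binary, k = 2)
          kr <- try_kappa(cohen_kappa, t)
        } else {
          t <- build_contingency(sub$aia_grade, sub$reader_grade, k = 4)
          kr <- try_kappa(function(x) weighted_kappa(x, scheme), t)
        }
        key <- paste(scope, stat, scale, sep = "|")
        comparisons[[key]] <- c(
          list(scope = scope, statistic = stat, scale = scale,
               counts = t$counts, n = t$n,
               percent_agreement = percent_agreement(t)),
          if (is.null(kr)) list(kappa = NA_real_) else
            kr[c("kappa", "se", "ci95", "po", "pe", "scheme", "label")]
        )
      }
    }
  }
  if (length(comparisons) == 0L) data_error("empty comparison set")
  structure(
    list(
      meta = list(
        n_videos = length(ids),
        statistics = statistics, scheme = scheme,
        percentile_method = percentile_method, segment_mode = segment_mode,
        n_segment_comparisons = sum(pairs$scope %in% seg_names &
                                      pairs$statistic == statistics[1]),
        n_videos_segments_dropped = length(dropped),
        dropped_video_ids = dropped
      ),
      pairs = pairs,
      comparisons = comparisons
    ),
    class = "agreement_report"
  )
}

try_kappa <- function(f, t) {
  tryCatch(f(t), ccecleanse_data_error = function(e) NULL)
}

#' Render a contingency table with percentage cells
#'
#' Each cell as `"n (pct)"` with percentages of the grand total, rounded
#' half-up to 2 decimals; includes row/column totals.
#'
#' @param t a `contingency_table`.
#' @return character matrix.
#' @export
render_contingency <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  cnt <- cbind(t$counts, Total = rowSums(t$counts))
  cnt <- rbind(cnt, Total = colSums(cnt))
  cells <- matrix(sprintf("%d (%s)", cnt, fmt_pct2(100 * cnt / t$n)),
                  nrow(cnt), dimnames = dimnames(cnt))
  cells
}

#' Render an agreement report as Markdown and flat tables
#'
#' @param report an `agreement_report` from [run_study()].
#' @return list with `markdown` (character scalar) and `summary` (data.frame,
#'   one row per comparison: scope, statistic, scale, n, percent agreement to
#'   1 decimal, kappa with 95% CI in the 2-decimal print style, label).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  comps <- report$comparisons
  summary <- do.call(rbind, lapply(comps, function(cm) {
    data.frame(
      scope = cm$scope, statistic = cm$statistic, scale = cm$scale,
      n = cm$n,
      percent_agreement = sprintf("%.1f", round_half_up(cm$percent_agreement, 1)),
      kappa = if (is.na(cm$kappa[1])) NA_character_ else
        sprintf("%s (%s-%s)", fmt_k2(cm$kappa), fmt_k2(cm$ci95[1]),
                fmt_k2(cm$ci95[2])),
      label = if (is.na(cm$kappa[1])) NA_character_ else cm$label,
      row.names = NULL
    )
  }))
  lines <- c(
    "# Bowel-cleansing agreement report", "",
    sprintf("Videos: %d; segment comparisons: %d; videos dropped from segmental scope: %d.",
            report$meta$n_videos, report$meta$n_segment_comparisons,
            report$meta$n_videos_segments_dropped),
    "",
    "| Scope | Statistic | Scale | n | Agreement (%) | kappa (95% CI) | Interpretation |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %d | %s | %s | %s |",
            summary$scope, summary$statistic, summary$scale, summary$n,
            summary$percent_agreement, summary$kappa, summary$label)
  )
  for (key in names(comps)) {
    cm <- comps[[key]]
    if (cm$scope != "total") next
    tbl <- render_contingency(as_contingency(cm$counts))
    lines <- c(lines, "", sprintf("## Total colon, %s (%s scale)",
                                  cm$statistic, cm$scale),
               "", utils::capture.output(print(tbl, quote = FALSE)))
  }
  list(markdown = paste(lines, collapse = "\n"), summary = summary)
}

#' Write / read an agreement report as JSON
#'
#' The JSON serialization is deterministic: re-running [run_study()] on the
#' same inputs and writing again yields byte-identical files.
#'
#' @param report an `agreement_report`.
#' @param path JSON file path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  out <- unclass(report)
  out$comparisons <- lapply(out$comparisons, function(cm) {
    cm$counts <- unname(apply(cm$counts, 1, as.list))
    cm
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) input_error(paste("no such file:", path))
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Load a study configuration from YAML
#'
#' Recognized fields: `frame_scores` and `reader_reports` (paths),
#' `statistics`, `scheme`, `percentile_method`, `segment_mode`, `out_dir`,
#' `seed`. Missing fields take the [run_study()] defaults.
#'
#' @param path YAML file.
#' @return named list of settings.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) input_error(paste("no such file:", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) config_error("study config must be a YAML mapping")
  cfg
}

#' Run a study from a configuration
#'
#' Reads the frame-score and reader-report files named by the configuration,
#' runs [run_study()], and (when `out_dir` is set) writes `report.json`,
#' `report.md` and `summary.csv`.
#'
#' @param config list from [read_study_config()] or built in code.
#' @return the `agreement_report`, invisibly when writing files.
#' @export
run_study_from_config <- function(config) {
  for (f in c("frame_scores", "reader_reports")) {
    if (is.null(config[[f]])) config_error(paste("study config missing field:", f))
  }
  scores <- read_frame_scores(config$frame_scores)
  reports <- read_reader_reports(config$reader_reports)
  report <- run_study(
    scores, reports,
    statistics = config$statistics %||% SUMMARY_STATS,
    scheme = config$scheme %||% "linear",
    percentile_method = config$percentile_method %||% "linear",
    segment_mode = config$segment_mode %||% "three"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
    rendered <- render_report(report)
    writeLines(rendered$markdown, file.path(config$out_dir, "report.md"))
    utils::write.csv(rendered$summary,
                     file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    return(invisible(report))
  }
  report
}
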