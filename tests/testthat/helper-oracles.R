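# Independent brute-force oracles used to cross-check the implementation.
# Deliberately written from first principles (explicit sorting and loops), not
# via the code paths they verify.

# Linear-interpolation quantile: h = (n-1)p + 1 on the sorted sample.
oracle_quantile_linear <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# Nearest-rank quantile: the ceil(n*p)-th order statistic.
oracle_quantile_nearest <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) s[max(1L, ceiling(n * pp))], numeric(1))
}

oracle_summary <- function(x, method = "linear") {
  q <- if (method == "linear") {
    oracle_quantile_linear(x, c(0.02, 0.25, 0.5, 0.75, 0.98))
  } else {
    oracle_quantile_nearest(x, c(0.02, 0.25, 0.5, 0.75, 0.98))
  }
  list(mean = sum(x) / length(x), median = q[3], q1 = q[2], q3 = q[4],
       p2 = q[1], p98 = q[5])
}

# Unweighted Cohen's kappa via explicit element loops.
oracle_kappa <- function(counts) {
  n <- sum(counts)
  k <- nrow(counts)
  po <- 0
  for (i in seq_len(k)) po <- po + counts[i, i] / n
  pe <- 0
  for (i in seq_len(k)) pe <- pe + (sum(counts[i, ]) / n) * (sum(counts[, i]) / n)
  (po - pe) / (1 - pe)
}

# Weighted kappa as 1 - sum((1-w) o) / sum((1-w) e), double loop.
oracle_weighted_kappa <- function(counts, scheme) {
  n <- sum(counts)
  k <- nrow(counts)
  num <- 0
  den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pen <- if (scheme == "linear") abs(i - j) / (k - 1) else (i - j)^2 / (k - 1)^2
      num <- num + pen * counts[i, j] / n
      den <- den + pen * (sum(counts[i, ]) / n) * (sum(counts[, j]) / n)
    }
  }
  1 - num / den
}

# Random contingency table with mass in more than one category.
random_table <- function(k, lambda = 4) {
  repeat {
    counts <- matrix(stats::rpois(k * k, lambda), k, k)
    if (sum(counts) == 0) next
    occupied <- union(which(rowSums(counts) > 0), which(colSums(counts) > 0))
    if (length(occupied) >= 2) return(counts)
  }
}

study_gcols <- paste0("grade_", c("cecum", "right", "transverse", "left", "rectum"))

# Overall 2-point marginals of a synthetic cohort, computed through the
# package's grading primitives.
cohort_marginals <- function(coh) {
  reader_nonacc <- mean(apply(coh$reader_reports[study_gcols], 1, min) == 1)
  mu <- tapply(coh$frame_scores$rating, coh$frame_scores$video_id, mean)
  aia_nonacc <- mean(grade_to_binary(rating_to_grade(mu)) == 1)
  c(reader = 100 * reader_nonacc, aia = 100 * aia_nonacc)
}
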