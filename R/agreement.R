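# Interobserver agreement: contingency tables, percent agreement, Cohen's
# kappa, weighted kappa, confidence intervals, interpretation bands.

#' Cross-tabulate paired algorithm/reader grades
#'
#' @param algorithm,reader integer vectors of equal length, categories in
#'   `1..k` (rows = algorithm, columns = reader). Pair order is irrelevant.
#' @param k number of categories (2 for the acceptability scale, 4 for the
#'   Leighton-Rex scale).
#' @param labels optional category labels for the dimnames.
#' @return A `contingency_table`: list with `counts` (k x k integer matrix),
#'   `k`, `n`.
#' @examples
#' build_contingency(c(1, 2, 2), c(1, 2, 1), k = 2)
#' @export
build_contingency <- function(algorithm, reader, k, labels = NULL) {
  if (length(algorithm) != length(reader) || length(algorithm) == 0L) {
    input_error("`algorithm` and `reader` must be non-empty and equal length")
  }
  if (!is_count(k) || k < 2) config_error("`k` must be an integer >= 2")
  a <- as.integer(algorithm)
  r <- as.integer(reader)
  bad <- which(is.na(a) | is.na(r) | a < 1 | a > k | r < 1 | r > k)
  if (length(bad)) {
    data_error(sprintf(
      "grade outside 1..%d in pair %d (algorithm %s, reader %s)",
      k, bad[1], algorithm[bad[1]], reader[bad[1]]))
  }
  if (is.null(labels)) {
    labels <- if (k == 2) BINARY_LABELS else if (k == 4) GRADE_LABELS
              else as.character(seq_len(k))
  }
  counts <- table(factor(a, levels = seq_len(k)), factor(r, levels = seq_len(k)))
  counts <- matrix(as.integer(counts), k, k,
                   dimnames = list(algorithm = labels, reader = labels))
  as_contingency(counts)
}

#' Construct a contingency table from a count matrix
#'
#' @param counts square matrix of nonnegative counts, rows = algorithm,
#'   columns = reader.
#' @return A `contingency_table`.
#' @export
as_contingency <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    input_error("`counts` must be a square matrix")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    input_error("`counts` must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) input_error("contingency table has zero total count")
  structure(list(counts = counts, k = nrow(counts), n = n),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table (%d x %d, n = %d), rows = algorithm\n",
              x$k, x$k, x$n))
  print(x$counts)
  invisible(x)
}

#' Observed percent agreement
#'
#' `100 * trace / n`: the share of pairs graded identically by both raters,
#' uncorrected for chance.
#'
#' @param t a `contingency_table`.
#' @return percentage in `[0, 100]` (full precision; round for display).
#' @export
percent_agreement <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  100 * sum(diag(t$counts)) / t$n
}

#' Agreement weight matrices
#'
#' `w[i, j] = 1` on the diagonal; off-diagonal penalties by scheme:
#' unweighted (0 off-diagonal), linear `1 - |i-j|/(k-1)` (Cicchetti-Allison)
#' or quadratic `1 - (i-j)^2/(k-1)^2` (Fleiss-Cohen).
#'
#' @param k number of categories (>= 2).
#' @param scheme `"unweighted"`, `"linear"` or `"quadratic"`.
#' @return k x k numeric weight matrix.
#' @export
kappa_weights <- function(k, scheme = c("unweighted", "linear", "quadratic")) {
  scheme <- match.arg(scheme)
  if (!is_count(k) || k < 2) config_error("`k` must be an integer >= 2")
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(scheme,
    unweighted = (d == 0) + 0,
    linear = 1 - d / (k - 1),
    quadratic = 1 - d^2 / (k - 1)^2
  )
}

# Core kappa machinery: weighted observed/expected agreement, the large-sample
# (Fleiss-Cohen-Everitt) standard error, and the Wald 95% CI. Identity weights
# reduce it to unweighted Cohen's kappa.
kappa_engine <- function(t, w, scheme) {
  p <- t$counts / t$n
  r <- rowSums(p)
  cl <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cl))
  if (pe >= 1 - 1e-12) {
    data_error("kappa undefined: expected agreement is 1 (all mass in one category)")
  }
  kappa <- (po - pe) / (1 - pe)
  wr <- as.vector(w %*% cl)        # E[w | algorithm row i]
  wc <- as.vector(crossprod(w, r)) # E[w | reader column j]
  m <- outer(wr, rep(1, t$k)) + outer(rep(1, t$k), wc)
  v <- (sum(p * (w * (1 - pe) - m * (1 - po))^2) -
          (po * pe - 2 * pe + po)^2) / (t$n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  ci <- pmax(-1, pmin(1, kappa + c(-1, 1) * stats::qnorm(0.975) * se))
  structure(
    list(kappa = kappa, po = po, pe = pe, se = se, ci95 = ci,
         percent_agreement = percent_agreement(t), scheme = scheme,
         label = interpret_kappa(kappa), n = t$n, k = t$k),
    class = "kappa_result"
  )
}

#' Cohen's kappa for a contingency table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po = trace/n` and chance agreement `pe` from the marginals. The
#' standard error is the large-sample (Fleiss-Cohen-Everitt) estimate and the
#' 95% CI is the Wald interval `kappa +/- 1.96 se`, truncated to `[-1, 1]`.
#'
#' @param t a `contingency_table`.
#' @return A `kappa_result`: `kappa`, `po`, `pe`, `se`, `ci95`,
#'   `percent_agreement`, `scheme`, `label` (interpretation band), `n`, `k`.
#' @examples
#' t <- as_contingency(matrix(c(26, 24, 196, 596), 2, byrow = TRUE))
#' cohen_kappa(t)
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  kappa_engine(t, kappa_weights(t$k, "unweighted"), "unweighted")
}

#' Weighted Cohen's kappa for ordinal scales
#'
#' Discounts near-miss disagreements with linear (default) or quadratic
#' weights; see [kappa_weights()]. For 2 categories both schemes coincide with
#' unweighted kappa.
#'
#' @param t a `contingency_table`.
#' @param scheme `"linear"` or `"quadratic"`.
#' @return A `kappa_result`.
#' @export
weighted_kappa <- function(t, scheme = c("linear", "quadratic")) {
  stopifnot(inherits(t, "contingency_table"))
  scheme <- match.arg(scheme)
  kappa_engine(t, kappa_weights(t$k, scheme), scheme)
}

#' Interpretation band of a kappa value
#'
#' Conventional agreement bands: after rounding to 2 decimals,
#' `<= .20` None, `.21-.39` Minimal, `.40-.59` Weak, `.60-.79` Moderate,
#' `.80-.90` Strong, `> .90` Almost perfect. Negative values fall in "None".
#' Rounding first makes the bands exhaustive (no gap between .20 and .21).
#'
#' @param kappa numeric vector in `[-1, 1]`.
#' @return character vector of labels.
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || anyNA(kappa) || any(abs(kappa) > 1 + 1e-9)) {
    input_error("`kappa` must be numeric in [-1, 1]")
  }
  k2 <- round_half_up(kappa, 2)
  ifelse(k2 <= 0.20, "None",
  ifelse(k2 <= 0.39, "Minimal",
  ifelse(k2 <= 0.59, "Weak",
  ifelse(k2 <= 0.79, "Moderate",
  ifelse(k2 <= 0.90, "Strong", "Almost perfect")))))
}

#' Bootstrap confidence interval for kappa
#'
#' Percentile bootstrap resampling the n pairs (multinomial over the table
#' cells). A cross-check for the asymptotic Wald interval of [cohen_kappa()].
#'
#' @param t a `contingency_table`.
#' @param scheme weighting scheme, as in [kappa_weights()].
#' @param B number of bootstrap resamples.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return numeric length-2: lower and upper percentile bounds.
#' @export
kappa_boot_ci <- function(t, scheme = "unweighted", B = 2000, seed = 1,
                          level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  w <- kappa_weights(t$k, scheme)
  p <- as.vector(t$counts) / t$n
  draws <- with_seed(seed, stats::rmultinom(B, t$n, p))
  ks <- apply(draws, 2, function(cnt) {
    tb <- as_contingency(matrix(cnt, t$k, t$k))
    tryCatch(kappa_engine(tb, w, scheme)$kappa, error = function(e) NA_real_)
  })
  alpha <- (1 - level) / 2
  unname(stats::quantile(ks, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Format a kappa result in the conventional 2-decimal style
#'
#' e.g. `".10 (.05-.16)"` — point estimate and 95% CI to 2 decimals without a
#' leading zero. Full precision stays in the `kappa_result` object.
#'
#' @param x a `kappa_result`.
#' @return character scalar.
#' @export
format_kappa <- function(x) {
  stopifnot(inherits(x, "kappa_result"))
  sprintf("%s (%s-%s)", fmt_k2(x$kappa), fmt_k2(x$ci95[1]), fmt_k2(x$ci95[2]))
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa (%s): %s   po = %.4f, pe = %.4f, agreement = %.1f%%\n  n = %d, interpretation: %s\n",
    x$scheme, format_kappa(x), x$po, x$pe, x$percent_agreement, x$n, x$label
  ))
  invisible(x)
}
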