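test_that("contingency tables count pairs and ignore order", {
  t <- build_contingency(c(1, 2), c(1, 2), k = 2)
  expect_equal(t$counts, matrix(c(1L, 0L, 0L, 1L), 2, 2,
                                dimnames = dimnames(t$counts)))
  expect_equal(t$n, 2)

  withr::with_seed(4, {
    a <- sample.int(4, 300, replace = TRUE)
    r <- sample.int(4, 300, replace = TRUE)
    t1 <- build_contingency(a, r, k = 4)
    perm <- sample(300)
    t2 <- build_contingency(a[perm], r[perm], k = 4)
    expect_identical(t1$counts, t2$counts)
  })
  expect_error(build_contingency(c(1, 5), c(1, 2), k = 4),
               regexp = "pair 2", class = "ccecleanse_data_error")
})

test_that("pairs reconstructed from the published counts rebuild the table", {
  tt <- study_contingency_tables()
  for (nm in c("mean", "median")) {
    cnt <- tt[[nm]]$counts
    a <- rep(rep(1:2, each = 2), times = as.vector(t(cnt)))
    r <- rep(rep(1:2, times = 2), times = as.vector(t(cnt)))
    rebuilt <- build_contingency(a, r, k = 2)
    expect_equal(unname(rebuilt$counts), unname(cnt))
    expect_equal(rebuilt$n, 842)
  }
})

test_that("percent agreement is the diagonal share", {
  expect_equal(percent_agreement(as_contingency(diag(5L))), 100)
  tt <- study_contingency_tables()
  expect_equal(round(percent_agreement(tt$mean), 1), 73.9)
  expect_equal(round(percent_agreement(tt$median), 1), 73.8)
})

test_that("kappa matches the brute-force oracle on random tables", {
  expect_equal(cohen_kappa(as_contingency(diag(10L, 3)))$kappa, 1)
  withr::with_seed(21, {
    for (i in 1:100) {
      k <- sample(2:5, 1)
      cnt <- random_table(k)
      t <- as_contingency(cnt)
      kr <- cohen_kappa(t)
      expect_lt(abs(kr$kappa - oracle_kappa(cnt)), 1e-12)
      expect_lte(kr$kappa, kr$po + 1e-12) # kappa never exceeds raw agreement
      # invariance under a simultaneous row/column permutation
      p <- sample(k)
      expect_lt(abs(cohen_kappa(as_contingency(cnt[p, p]))$kappa - kr$kappa),
                1e-12)
      for (sch in c("linear", "quadratic")) {
        expect_lt(abs(weighted_kappa(t, sch)$kappa -
                        oracle_weighted_kappa(cnt, sch)), 1e-12)
      }
    }
  })
})

test_that("2x2 weighted kappa degenerates to unweighted", {
  withr::with_seed(22, {
    for (i in 1:50) {
      t <- as_contingency(random_table(2))
      expect_lt(abs(weighted_kappa(t, "linear")$kappa - cohen_kappa(t)$kappa),
                1e-12)
      expect_lt(abs(weighted_kappa(t, "quadratic")$kappa - cohen_kappa(t)$kappa),
                1e-12)
    }
  })
  t4 <- as_contingency(diag(3L, 4))
  expect_equal(weighted_kappa(t4, "linear")$kappa, 1)
  expect_equal(weighted_kappa(t4, "quadratic")$kappa, 1)
})

test_that("quadratic weights reward adjacent-only disagreement more than linear", {
  # disagreements concentrated one step off the diagonal
  adj <- matrix(0L, 4, 4)
  diag(adj) <- c(30L, 40L, 40L, 30L)
  for (i in 1:3) {
    adj[i, i + 1] <- 12L
    adj[i + 1, i] <- 12L
  }
  t <- as_contingency(adj)
  expect_gt(weighted_kappa(t, "quadratic")$kappa,
            weighted_kappa(t, "linear")$kappa)
  expect_gt(weighted_kappa(t, "linear")$kappa, cohen_kappa(t)$kappa)
})

test_that("asymptotic and bootstrap intervals agree with the published CI", {
  tt <- study_contingency_tables()
  km <- cohen_kappa(tt$mean)
  expect_equal(round(km$ci95, 2), c(0.05, 0.16))
  expect_equal(round(cohen_kappa(tt$median)$ci95, 2), c(0.05, 0.18))
  boot <- kappa_boot_ci(tt$mean, B = 2000, seed = 17)
  expect_lt(abs(boot[1] - 0.05), 0.02)
  expect_lt(abs(boot[2] - 0.16), 0.02)
  expect_true(format_kappa(km) == ".10 (.05-.16)")
})

test_that("kappa is undefined when all mass sits in one category", {
  one <- matrix(0L, 2, 2)
  one[2, 2] <- 50L
  expect_error(cohen_kappa(as_contingency(one)), class = "ccecleanse_data_error")
})

test_that("interpretation bands are exhaustive after 2-decimal rounding", {
  expect_identical(interpret_kappa(c(0.10, 0.12, -0.20, -1)),
                   rep("None", 4))
  expect_identical(interpret_kappa(0.69), "Moderate")
  expect_identical(interpret_kappa(c(0.20, 0.205, 0.21)),
                   c("None", "Minimal", "Minimal"))
  expect_identical(interpret_kappa(c(0.40, 0.59, 0.60, 0.79, 0.80, 0.90)),
                   c("Weak", "Weak", "Moderate", "Moderate", "Strong", "Strong"))
  expect_identical(interpret_kappa(c(0.905, 1)), rep("Almost perfect", 2))
  expect_error(interpret_kappa(1.2), class = "ccecleanse_input_error")
})

test_that("independent raters give near-zero kappa", {
  withr::with_seed(31, {
    a <- sample.int(2, 10000, replace = TRUE, prob = c(0.06, 0.94))
    r <- sample.int(2, 10000, replace = TRUE, prob = c(0.26, 0.74))
    k <- cohen_kappa(build_contingency(a, r, k = 2))$kappa
    expect_lt(abs(k), 0.05)
  })
})
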