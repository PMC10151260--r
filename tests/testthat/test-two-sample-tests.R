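test_that("f_test matches var.test and hand arithmetic", {
  expect_equal(f_test(c(0, 2), c(0, 4))$statistic, c(F = 0.25))
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    for (alt in c("two.sided", "less", "greater")) {
      mine <- f_test(x, y, alternative = alt)
      ref <- stats::var.test(x, y, alternative = alt)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
      expect_equal(unname(mine$statistic), unname(ref$statistic))
    }
  }
})

test_that("f_test edge behaviour: equal variances, ratio0, degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(f_test(x, x + 10)$p.value, 1)       # equal variances, equal df
  expect_equal(f_test(c(0, 2), c(0, 4), ratio0 = 0.25)$statistic, c(F = 1))
  expect_error(f_test(c(1, 1), c(1, 2)), "zero sample variance")
  # n = 3 per group: two-sided alpha=.05 rejection boundary is F = 39.0
  expect_lt(abs(2 * pf(39.0, 2, 2, lower.tail = FALSE) - 0.05), 1e-6)
})

test_that("two-sided F p-value doubles the one-sided tail when F >= 1, equal df", {
  set.seed(4)
  x <- rnorm(10, sd = 2); y <- rnorm(10)
  stopifnot(var(x) > var(y))
  expect_equal(f_test(x, y, "two.sided")$p.value,
               min(1, 2 * f_test(x, y, "greater")$p.value))
})

test_that("welch_df matches the Satterthwaite formula and its bounds", {
  expect_equal(welch_df(2, 2, 8, 8), 14)            # symmetric: 2(n-1)
  expect_equal(welch_df(25, 1, 15, 15),
               (26 / 15)^2 / (((25 / 15)^2 + (1 / 15)^2) / 14))
  expect_equal(welch_df(5, 0, 9, 12), 8)            # one-variance limit: n1 - 1
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    df <- welch_df(runif(1, .1, 9), runif(1, .1, 9), n1, n2)
    expect_gte(df, min(n1, n2) - 1)
    expect_lte(df, n1 + n2 - 2 + 1e-12)
  }
  expect_error(welch_df(0, 0, 5, 5), "degenerate")
})

test_that("welch_t_test matches t.test in both variance modes", {
  set.seed(6)
  x <- rnorm(12); y <- rnorm(17, 1, 2)
  for (ve in c(TRUE, FALSE)) for (alt in c("two.sided", "less", "greater")) {
    mine <- welch_t_test(x, y, var.equal = ve, alternative = alt)
    ref <- stats::t.test(x, y, var.equal = ve, alternative = alt)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
    expect_equal(unname(mine$parameter), unname(ref$parameter))
  }
  expect_equal(welch_t_test(x, x)$statistic, c(t = 0))
  # equal n: same statistic in both modes, only df differ
  y2 <- rnorm(12, sd = 3)
  expect_equal(unname(welch_t_test(x, y2, TRUE)$statistic),
               unname(welch_t_test(x, y2, FALSE)$statistic))
  expect_error(welch_t_test(c(1, 1), c(1, 1), var.equal = TRUE), "degenerate")
})

test_that("walsh_means enumerates all pairwise averages with replacement", {
  expect_equal(sort(walsh_means(c(1, 3))), c(1, 2, 3))
  expect_length(walsh_means(rnorm(5)), 15)
  expect_equal(walsh_means(rep(2, 4)), rep(2, 10))
  x <- c(4, 1, 7)
  expect_setequal(walsh_means(x),
                  c(4, 1, 7, 2.5, 5.5, 4))
})

test_that("ansari_bradley_test matches stats::ansari.test on tie-free data", {
  set.seed(7)
  for (i in 1:15) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1), sd = 2)
    mine <- ansari_bradley_test(x, y, mode = "exact")
    ref <- stats::ansari.test(x, y)
    # R always scores x; compare only when x is the scored group
    if (mine$scored_group == "x") {
      expect_equal(unname(mine$statistic), unname(ref$statistic))
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    }
    # approximate path agrees with R's large-sample p on tie-free data
    mine_a <- ansari_bradley_test(x, y, mode = "approximate")
    ref_a <- stats::ansari.test(x, y, exact = FALSE)
    if (mine_a$scored_group == "x")
      expect_equal(mine_a$p.value, ref_a$p.value, tolerance = 1e-10)
  }
})

test_that("extreme-position configuration attains the exact support minimum", {
  # group 1 occupies the five outermost positions of the pooled sorted sample
  x <- c(1, 2, 98, 99, 100)   # scores 1,2 and 3,2,1
  y <- c(40, 45, 50, 55, 60)  # middle positions
  res <- ansari_bradley_test(x, y, alternative = "greater", mode = "exact")
  expect_equal(unname(res$statistic), 9)
  expect_equal(res$p.value, 2 / 252, tolerance = 1e-12)
})

test_that("median alignment removes location shifts", {
  set.seed(8)
  x <- rnorm(9); y <- rnorm(11, sd = 2)
  r1 <- suppressWarnings(ansari_bradley_test(x, y, align_medians = TRUE))
  r2 <- suppressWarnings(ansari_bradley_test(x + 100, y, align_medians = TRUE))
  expect_equal(unname(r1$statistic), unname(r2$statistic))
  expect_equal(r1$p.value, r2$p.value)
  expect_warning(ansari_bradley_test(x, y, align_medians = TRUE),
                 "distribution-free")
})

test_that("ties switch the Ansari-Bradley test to the approximate null", {
  x <- c(1, 2, 2, 5); y <- c(2, 3, 4, 6)
  expect_warning(res <- ansari_bradley_test(x, y, mode = "exact"), "ties")
  expect_false(res$exact)
  expect_error(ansari_bradley_test(rep(1, 4), rep(1, 5)), "identical")
})

test_that("moses_test subset dispersion statistics behave as specified", {
  # D of subset {1,2,3} is 2; n=11 with subset size 3 discards 2 observations
  set.seed(9)
  m <- moses_test(rnorm(11), rnorm(12), subset_size = 3, repartitions = 20,
                  seed = 1)
  expect_equal(unname(m$discarded), c(2L, 0L))
  expect_error(moses_test(rnorm(5), rnorm(20), subset_size = 3),
               "at least 2 subsets")
  # reproducible for a fixed seed
  x <- rnorm(24); y <- rnorm(24)
  m1 <- moses_test(x, y, seed = 42, repartitions = 50)
  m2 <- moses_test(x, y, seed = 42, repartitions = 50)
  expect_identical(m1$p.value, m2$p.value)
})

test_that("moses_test detects a 3x scale difference one-sidedly", {
  set.seed(10)
  x <- rnorm(60)
  y <- 3 * rnorm(60)
  m <- moses_test(x, y, repartitions = 100, alternative = "less", seed = 2)
  expect_lt(m$p.value, 0.01)
  # and the opposite one-sided alternative is not significant
  m2 <- moses_test(x, y, repartitions = 100, alternative = "greater", seed = 2)
  expect_gt(m2$p.value, 0.5)
})

test_that("jackknife identities: identical samples, exact scale law, shifts", {
  set.seed(12)
  x <- rnorm(15)
  same <- jackknife_test(x, x)
  expect_equal(unname(same$statistic), 0)
  expect_equal(unname(same$estimate), 1)
  expect_equal(same$p.value, 1)
  # y = c x gives gamma^2 = c^2 exactly
  for (cc in c(0.5, 2, 7)) {
    j <- jackknife_test(x, cc * x)
    expect_equal(unname(j$estimate), cc^2, tolerance = 1e-12)
  }
  # adding a constant to one group changes nothing on that side
  y <- rnorm(15, sd = 2)
  expect_equal(jackknife_test(x + 5, y)$statistic,
               jackknife_test(x, y)$statistic)
  expect_error(jackknife_test(c(1, 2), rnorm(5)), ">= 3")
  expect_error(jackknife_test(c(1, 1, 1, 5), rnorm(5)), "leave-one-out")
})

test_that("jackknife gamma^2 is a consistent variance-ratio estimator", {
  set.seed(13)
  r <- 2.5
  est <- replicate(1000, {
    unname(jackknife_test(rnorm(200), rnorm(200, sd = sqrt(r)))$estimate)
  })
  expect_lt(abs(median(est) - r) / r, 0.05)
})

test_that("all two-sample scale tests are invariant to common rescaling", {
  set.seed(14)
  x <- rnorm(12); y <- rnorm(14, sd = 1.7)
  cc <- 3.7
  expect_equal(f_test(x, y)$p.value, f_test(cc * x, cc * y)$p.value)
  expect_equal(ansari_bradley_test(x, y)$p.value,
               ansari_bradley_test(cc * x, cc * y)$p.value)
  expect_equal(jackknife_test(x, y)$p.value,
               jackknife_test(cc * x, cc * y)$p.value, tolerance = 1e-12)
  expect_equal(moses_test(x, y, seed = 3)$p.value,
               moses_test(cc * x, cc * y, seed = 3)$p.value)
})
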