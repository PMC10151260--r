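random_groups <- function(k = 3, nmin = 4, nmax = 15, sd_range = c(0.5, 3)) {
  vals <- lapply(seq_len(k), function(i)
    rnorm(sample(nmin:nmax, 1), sd = runif(1, sd_range[1], sd_range[2])))
  names(vals) <- letters[seq_len(k)]
  grouped_sample(vals)
}

test_that("Levene W equals the one-way ANOVA F on the Z deviations", {
  set.seed(21)
  for (i in 1:100) {
    gs <- random_groups(k = sample(2:5, 1))
    for (ctr in c("mean", "median", "trimmed", "rank")) {
      mine <- levene_test(gs, ctr)
      # oracle: recompute Z independently and feed stats::oneway.test
      vals <- gs
      if (ctr == "rank") {
        pooled <- unlist(gs, use.names = FALSE)
        r <- rank(pooled, ties.method = "average")
        vals <- split(r, rep(seq_along(gs), vapply(gs, length, 0L)))
      }
      cfun <- switch(ctr, mean = mean, rank = mean, median = median,
                     trimmed = function(v) {
                       g <- floor(0.25 * length(v)); s <- sort(v)
                       mean(s[(g + 1):(length(v) - g)])
                     })
      z <- unlist(lapply(vals, function(v) abs(v - cfun(v))))
      g <- rep(names(gs), vapply(gs, length, 0L))
      ref <- stats::oneway.test(z ~ factor(g), var.equal = TRUE)
      expect_equal(unname(mine$statistic), unname(ref$statistic),
                   tolerance = 1e-10, info = ctr)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10, info = ctr)
    }
  }
})

test_that("Levene center variants behave as documented", {
  # identical multisets across groups: between-group variation of Z is 0
  g <- c(1, 2, 5, 9)
  gs <- grouped_sample(list(a = g, b = sample(g), c = g))
  res <- levene_test(gs, "mean")
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  # 2-point groups make every |Y - mean| constant within group: degenerate
  expect_error(levene_test(grouped_sample(list(a = c(0, 2), b = c(0, 20)))),
               "degenerate")
  # brown_forsythe_test is byte-identical to the median-centred variant
  set.seed(22)
  gs2 <- random_groups()
  expect_identical(brown_forsythe_test(gs2), levene_test(gs2, "median"))
  # trimming must leave at least one value
  expect_error(levene_test(grouped_sample(list(a = c(1, 2), b = c(1, 3))),
                           "trimmed", trim = 0.5), "trim")
})

test_that("bartlett_test matches stats::bartlett.test and the hand example", {
  set.seed(23)
  for (i in 1:20) {
    gs <- random_groups(k = sample(2:4, 1))
    df <- as.data.frame(gs)
    mine <- bartlett_test(gs)
    ref <- stats::bartlett.test(df$value, factor(df$group))
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
  # k = 2, n = 11 each, s^2 = 1 and 2: chi^2 = (20 ln 1.5 - 10 ln 2) / 1.05
  x <- scale(rnorm(11)) * 1              # variance exactly 1
  y <- scale(rnorm(11)) * sqrt(2)        # variance exactly 2
  res <- bartlett_test(grouped_sample(list(a = as.numeric(x), b = as.numeric(y))))
  expect_equal(unname(res$statistic),
               (20 * log(1.5) - 10 * log(2)) / 1.05, tolerance = 1e-10)
  # all equal variances -> statistic 0
  res0 <- bartlett_test(grouped_sample(list(a = as.numeric(x),
                                            b = as.numeric(x) + 3)))
  expect_equal(unname(res0$statistic), 0, tolerance = 1e-12)
  expect_error(bartlett_test(grouped_sample(list(a = c(1, 1), b = c(1, 2)))),
               "zero variance")
})

test_that("hartley_test decisions follow the computed Fmax critical values", {
  gs <- grouped_sample(list(a = c(1, 2, 3), b = c(1, 2, 3) + 5))
  h <- hartley_test(gs)
  expect_equal(unname(h$statistic), 1)
  expect_false(h$reject)
  expect_equal(h$critical_value, 39.0, tolerance = 1e-3)  # k=2, df=2
  gs3 <- grouped_sample(list(a = c(1, 2, 3), b = c(0, 2, 4), c = c(-3, 2, 7)))
  h3 <- hartley_test(gs3)
  expect_equal(h3$critical_value, 87.5, tolerance = 5e-3) # k=3, df=2
  expect_equal(unname(h3$statistic), 25)                  # variances 1, 4, 25
  expect_false(h3$reject)
  # p-value and decision are consistent
  expect_equal(h3$reject, h3$p.value < h3$alpha)
  # unbalanced design: smaller df used, flagged in the method string
  gs_u <- grouped_sample(list(a = rnorm(4), b = rnorm(9)))
  expect_match(hartley_test(gs_u)$method, "unbalanced")
})

test_that("cochran_c_test statistics, bound and decision", {
  gs <- grouped_sample(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
  cc <- cochran_c_test(gs)
  expect_equal(unname(cc$C), rep(1 / 3, 3))   # all variances equal
  expect_false(cc$reject)
  # one dominant variance approaches C = 1 and rejects
  gs2 <- grouped_sample(list(a = c(0, 1e-4, 2e-4), b = c(0, 1e-4, 2e-4),
                             c = c(0, 50, 100)))
  cc2 <- cochran_c_test(gs2)
  expect_gt(unname(cc2$statistic), cc2$upper_limit)
  expect_true(cc2$reject)
  expect_identical(cc2$tested_group, "c")
  # k=2, n=3: upper limit is 39/40
  gs_pair <- grouped_sample(list(a = c(1, 2, 3), b = c(1, 3, 5)))
  expect_equal(cochran_c_test(gs_pair)$upper_limit, 39 / 40, tolerance = 1e-6)
  # p-value inversion agrees with the critical-value decision
  set.seed(24)
  for (i in 1:20) {
    g <- grouped_sample(list(a = rnorm(5), b = rnorm(5, sd = runif(1, 1, 4)),
                             c = rnorm(5)))
    r <- cochran_c_test(g)
    expect_equal(r$reject, r$p.value < r$alpha, info = i)
  }
  expect_error(cochran_c_test(grouped_sample(list(a = rnorm(3), b = rnorm(4)))),
               "equal group sizes")
})

test_that("fligner_killeen_test matches stats::fligner.test", {
  set.seed(25)
  for (i in 1:20) {
    gs <- random_groups(k = sample(2:4, 1))
    df <- as.data.frame(gs)
    mine <- fligner_killeen_test(gs)
    ref <- stats::fligner.test(df$value, factor(df$group))
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
  # normal scores for N = 3: qnorm(0.625), qnorm(0.75), qnorm(0.875)
  expect_equal(stats::qnorm((1 + (1:3) / 4) / 2),
               c(0.3186394, 0.6744898, 1.1503494), tolerance = 1e-6)
  # identical multisets across groups give statistic 0
  g <- c(1, 3, 8, 9)
  gs0 <- grouped_sample(list(a = g, b = g))
  expect_equal(unname(fligner_killeen_test(gs0)$statistic), 0)
  # invariant to per-group location shifts (exact in exact arithmetic; the
  # shift can reorder nearly-tied deviations through floating rounding, so a
  # modest tolerance is used)
  gs1 <- random_groups()
  shifted <- grouped_sample(Map(`+`, gs1, as.list(c(10, -4, 0.3))))
  expect_equal(unname(fligner_killeen_test(gs1)$statistic),
               unname(fligner_killeen_test(shifted)$statistic),
               tolerance = 1e-3)
})

test_that("welch_anova matches oneway.test and the k = 2 Welch-t identity", {
  set.seed(26)
  for (i in 1:100) {
    gs <- random_groups(k = sample(2:4, 1))
    df <- as.data.frame(gs)
    mine <- welch_anova(gs)
    ref <- stats::oneway.test(value ~ factor(group), df)
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    if (attr(gs, "k") == 2) {
      tt <- welch_t_test(gs[[1]], gs[[2]], var.equal = FALSE)
      expect_equal(unname(mine$statistic), unname(tt$statistic)^2,
                   tolerance = 1e-10)
      expect_equal(unname(mine$parameter["df2"]), unname(tt$parameter),
                   tolerance = 1e-10)
    }
  }
})

test_that("one_way_anova matches the pooled-t identity and oneway.test", {
  set.seed(27)
  gs <- random_groups(k = 2)
  a <- one_way_anova(gs)
  tt <- welch_t_test(gs[[1]], gs[[2]], var.equal = TRUE)
  expect_equal(unname(a$statistic), unname(tt$statistic)^2, tolerance = 1e-12)
  gs3 <- random_groups(k = 3)
  df <- as.data.frame(gs3)
  ref <- stats::oneway.test(value ~ factor(group), df, var.equal = TRUE)
  expect_equal(unname(one_way_anova(gs3)$statistic), unname(ref$statistic),
               tolerance = 1e-12)
  expect_error(one_way_anova(grouped_sample(list(a = c(2, 2), b = c(2, 2)))),
               "degenerate")
  # starting from groups with identical means, shifting one group away
  # increases F monotonically in |delta|
  base <- lapply(gs3, function(v) v - mean(v))
  f_at <- vapply(c(0.5, 1, 2, 4), function(d) {
    g <- base; g[[1]] <- g[[1]] + d
    unname(one_way_anova(grouped_sample(g))$statistic)
  }, 0)
  expect_true(all(diff(f_at) > 0))
})

test_that("multi-sample statistics are location- and scale-equivariant", {
  set.seed(28)
  gs <- grouped_sample(lapply(1:3, function(i) rnorm(8, sd = i)))  # balanced
  shift <- grouped_sample(lapply(gs, function(v) v + 11.3))
  scaled <- grouped_sample(lapply(gs, function(v) v * 2.6))
  tests <- list(levene = function(g) levene_test(g, "mean"),
                bartlett = bartlett_test, hartley = hartley_test,
                cochran = cochran_c_test, fligner = fligner_killeen_test)
  for (nm in names(tests)) {
    f <- tests[[nm]]
    # rank-based statistics can move slightly when floating-point shifts
    # reorder nearly-tied deviations; everything else is exact
    tol <- if (nm == "fligner") 1e-3 else 1e-9
    expect_equal(unname(f(gs)$statistic), unname(f(shift)$statistic),
                 tolerance = tol, info = nm)
    expect_equal(unname(f(gs)$statistic), unname(f(scaled)$statistic),
                 tolerance = tol, info = nm)
  }
})
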