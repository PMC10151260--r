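# trimmed per-group center: drop floor(p * n) values from each tail
trimmed_center <- function(v, p) {
  n <- length(v)
  g <- floor(p * n)
  if (n - 2 * g < 1)
    stop("trimming removes every observation (n = ", n, ", trim = ", p, ")")
  s <- sort(v)
  mean(s[(g + 1):(n - g)])
}

#' Levene's test for homogeneity of variance (with variants)
#'
#' Replaces each observation by its absolute deviation from a per-group
#' centre, \eqn{Z_{ij} = |Y_{ij} - c_i|}, and runs a one-way ANOVA F statistic
#' on the Z's:
#' \deqn{W = \frac{(N-k)}{(k-1)}
#'   \frac{\sum_i n_i (\bar Z_{i.} - \bar Z_{..})^2}
#'        {\sum_i \sum_j (Z_{ij} - \bar Z_{i.})^2}}
#' referred to F(k-1, N-k). The centre determines the variant:
#' `"mean"` is the classical Levene test, `"median"` the Brown-Forsythe test,
#' `"trimmed"` uses a symmetric trimmed mean (default: 25% from each tail),
#' and `"rank"` first replaces all observations by their pooled midranks and
#' then applies the mean-centred statistic (the non-parametric variant).
#' Because the statistic works on deviations rather than sample variances it
#' is far less sensitive to outliers than the F or Bartlett tests.
#'
#' @param x a [grouped_sample()] (or coercible).
#' @param center `"mean"`, `"median"`, `"trimmed"`, or `"rank"`.
#' @param trim trimmed fraction per tail when `center = "trimmed"`.
#' @return an object of class `htest`.
#' @export
levene_test <- function(x, center = c("mean", "median", "trimmed", "rank"),
                        trim = 0.25) {
  center <- match.arg(center)
  x <- as_grouped_sample(x)
  k <- attr(x, "k"); N <- attr(x, "N")
  vals <- x
  if (center == "rank") {
    pooled <- unlist(x, use.names = FALSE)
    r <- rank(pooled, ties.method = "average")
    vals <- split(r, rep(seq_len(k), vapply(x, length, 0L)))
  }
  centre_fun <- switch(center,
                       mean = mean, rank = mean,
                       median = stats::median,
                       trimmed = function(v) trimmed_center(v, trim))
  Z <- lapply(vals, function(v) abs(v - centre_fun(v)))
  ni <- vapply(Z, length, 0L)
  zbar_i <- vapply(Z, mean, 0)
  zbar <- sum(unlist(Z)) / N
  between <- sum(ni * (zbar_i - zbar)^2)
  within <- sum(vapply(seq_len(k), function(i) sum((Z[[i]] - zbar_i[i])^2), 0))
  if (within <= 0)
    stop("degenerate input: zero within-group variation of |Y - center|")
  W <- (N - k) / (k - 1) * between / within
  variant <- switch(center,
                    mean = "Levene's test (mean center)",
                    median = "Brown-Forsythe test (median center)",
                    trimmed = sprintf("Levene's test (trimmed mean, %g%% per tail)",
                                      100 * trim),
                    rank = "Rank-based Levene's test")
  htest_result(statistic = c(W = W),
               parameter = c(df1 = k - 1, df2 = N - k),
               p.value = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
               method = variant, alternative = "two.sided",
               data.name = "grouped data")
}

#' Brown-Forsythe test
#'
#' Alias for [levene_test()] with `center = "median"`.
#'
#' @inheritParams levene_test
#' @return an object of class `htest`.
#' @export
brown_forsythe_test <- function(x) levene_test(x, center = "median")

#' Bartlett's test for homogeneity of variance
#'
#' Likelihood-ratio-derived test for k normal groups:
#' \deqn{\chi^2 = \frac{(N-k)\ln s_p^2 - \sum_i (n_i-1)\ln s_i^2}
#'   {1 + \frac{1}{3(k-1)}\left(\sum_i \frac{1}{n_i-1} - \frac{1}{N-k}\right)}}
#' referred to chi-square(k-1). The numerator is the (n_i - 1)-weighted sum of
#' log ratios of the pooled variance to each group variance, so it is zero
#' exactly when all group variances agree. Sensitive to non-normality.
#'
#' @param x a [grouped_sample()] (or coercible).
#' @return an object of class `htest`.
#' @export
bartlett_test <- function(x) {
  x <- as_grouped_sample(x)
  k <- attr(x, "k"); N <- attr(x, "N")
  ni <- vapply(x, length, 0L)
  si2 <- vapply(x, stats::var, 0)
  if (any(si2 == 0)) stop("degenerate input: a group has zero variance")
  sp2 <- sum((ni - 1) * si2) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(si2))
  corr <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  stat <- num / corr
  htest_result(statistic = c("chi-squared" = stat),
               parameter = c(df = k - 1),
               p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
               method = "Bartlett's test", alternative = "two.sided",
               data.name = "grouped data")
}

#' Hartley's Fmax test for homogeneity of variance
#'
#' Compares \eqn{F_{max}}, the ratio of the largest to the smallest group
#' sample variance, against the Fmax distribution for k groups on df = n - 1
#' degrees of freedom (balanced design). For unbalanced input the conservative
#' convention df = min(n_i) - 1 is used. Both a p-value (via [fmax_cdf()]) and
#' the critical-value decision (via [fmax_quantile()]) are reported; they
#' always agree. Assumes normality.
#'
#' @param x a [grouped_sample()] (or coercible).
#' @param alpha level for the critical-value decision.
#' @return an object of class `htest`; components `critical_value` and
#'   `reject` carry the table-style decision.
#' @export
hartley_test <- function(x, alpha = 0.05) {
  x <- as_grouped_sample(x)
  k <- attr(x, "k")
  ni <- vapply(x, length, 0L)
  si2 <- vapply(x, stats::var, 0)
  if (min(si2) == 0) stop("degenerate input: a group has zero variance")
  fmax <- max(si2) / min(si2)
  df <- min(ni) - 1
  crit <- fmax_quantile(alpha, k, df)
  p <- 1 - fmax_cdf(fmax, k, df)
  htest_result(statistic = c(Fmax = fmax),
               parameter = c(df = df, k = k),
               p.value = p,
               method = if (length(unique(ni)) == 1L)
                 "Hartley's Fmax test" else
                 "Hartley's Fmax test (unbalanced: smallest df used)",
               alternative = "two.sided", data.name = "grouped data",
               critical_value = crit, alpha = alpha, reject = fmax > crit)
}

#' Cochran's C test for an outlying variance
#'
#' Tests whether one group's variance is exceptionally large relative to the
#' others via \eqn{C_j = s_j^2 / \sum_i s_i^2}. Unlike the other tests in this
#' package it does not test global homogeneity: it flags one large variance at
#' a time, with a one-sided alternative. The default tests the largest
#' variance against the Bonferroni-adjusted bound [cochran_upper_limit()].
#' Requires a balanced design and normality.
#'
#' @param x a [grouped_sample()] (or coercible) with equal group sizes.
#' @param alpha test level.
#' @param which `"max"` (default: test the largest variance) or the index /
#'   name of a specific group.
#' @return an object of class `htest`; components `C` (all per-group values),
#'   `upper_limit`, `reject`, `tested_group`.
#' @export
cochran_c_test <- function(x, alpha = 0.05, which = "max") {
  x <- as_grouped_sample(x)
  k <- attr(x, "k")
  ni <- vapply(x, length, 0L)
  if (length(unique(ni)) != 1L)
    stop("Cochran's C test requires equal group sizes; ",
         "use Levene's or Bartlett's test for unbalanced designs")
  n <- ni[1]
  si2 <- vapply(x, stats::var, 0)
  tot <- sum(si2)
  if (tot <= 0) stop("degenerate input: all group variances are zero")
  C <- si2 / tot
  j <- if (identical(which, "max")) which.max(C)
       else if (is.character(which)) match(which, names(x))
       else as.integer(which)
  if (is.na(j) || j < 1 || j > k) stop("unknown group in `which`")
  cul <- cochran_upper_limit(alpha, n, k)
  # exact inversion of the bound: C > CUL  <=>  (k-1)C/(1-C) > F*
  fj <- (k - 1) * C[j] / (1 - C[j])
  p <- min(1, k * stats::pf(fj, n - 1, (k - 1) * (n - 1), lower.tail = FALSE))
  htest_result(statistic = c(C = unname(C[j])),
               parameter = c(n = n, k = k),
               p.value = p,
               method = "Cochran's C test (one-sided outlier-variance test)",
               alternative = "greater", data.name = "grouped data",
               C = C, upper_limit = cul, alpha = alpha,
               reject = unname(C[j]) > cul, tested_group = names(x)[j])
}

#' Fligner-Killeen normal-scores test
#'
#' Rank-based scale test robust to non-normality: absolute deviations from the
#' per-group medians \eqn{|Y_{ij} - \tilde Y_i|} are pooled and ranked
#' (midranks for ties), each rank m mapped to the normal score
#' \eqn{a_{N,m} = \Phi^{-1}((1 + m/(N+1))/2)}, and the statistic
#' \deqn{x_0^2 = \sum_i n_i (\bar A_i - \bar a)^2 / V^2}
#' (with \eqn{V^2} the variance of all scores, N-1 denominator) is referred to
#' chi-square(k-1). Because only ranks of median-centred deviations enter,
#' extreme values cannot dominate the statistic.
#'
#' @param x a [grouped_sample()] (or coercible).
#' @return an object of class `htest`.
#' @export
fligner_killeen_test <- function(x) {
  x <- as_grouped_sample(x)
  k <- attr(x, "k"); N <- attr(x, "N")
  dev <- lapply(x, function(v) abs(v - stats::median(v)))
  pooled <- unlist(dev, use.names = FALSE)
  a <- stats::qnorm((1 + rank(pooled, ties.method = "average") / (N + 1)) / 2)
  grp <- rep(seq_len(k), vapply(x, length, 0L))
  ni <- vapply(x, length, 0L)
  abar_i <- vapply(split(a, grp), mean, 0)
  abar <- mean(a)
  v2 <- sum((a - abar)^2) / (N - 1)
  if (v2 <= 0)
    stop("degenerate input: all median-centred deviations are tied")
  stat <- sum(ni * (abar_i - abar)^2) / v2
  htest_result(statistic = c("chi-squared" = stat),
               parameter = c(df = k - 1),
               p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
               method = "Fligner-Killeen test", alternative = "two.sided",
               data.name = "grouped data")
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances. With
#' weights \eqn{w_i = n_i / s_i^2}, \eqn{w = \sum w_i} and weighted grand mean
#' \eqn{\bar Y' = \sum w_i \bar Y_i / w}, the statistic is
#' \deqn{F = \frac{\frac{1}{k-1}\sum_i w_i (\bar Y_i - \bar Y')^2}
#'   {1 + \frac{2(k-2)}{k^2-1}\sum_i \frac{1}{n_i-1}(1 - w_i/w)^2}}
#' referred to F(k-1, df) with
#' \eqn{df = (k^2-1) / [3 \sum_i (1/(n_i-1)) (1 - w_i/w)^2]}.
#' This is the location test to use downstream when a homogeneity test has
#' rejected equal variances.
#'
#' @param x a [grouped_sample()] (or coercible).
#' @return an object of class `htest`.
#' @export
welch_anova <- function(x) {
  x <- as_grouped_sample(x)
  k <- attr(x, "k")
  ni <- vapply(x, length, 0L)
  si2 <- vapply(x, stats::var, 0)
  if (any(si2 == 0)) stop("degenerate input: a group has zero variance")
  wi <- ni / si2
  w <- sum(wi)
  ybar_i <- vapply(x, mean, 0)
  yprime <- sum(wi * ybar_i) / w
  lam <- sum((1 / (ni - 1)) * (1 - wi / w)^2)
  Fstat <- (sum(wi * (ybar_i - yprime)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2 <- (k^2 - 1) / (3 * lam)
  htest_result(statistic = c(F = Fstat),
               parameter = c(df1 = k - 1, df2 = df2),
               p.value = stats::pf(Fstat, k - 1, df2, lower.tail = FALSE),
               method = "Welch's ANOVA (unequal variances)",
               alternative = "two.sided", data.name = "grouped data")
}

#' Classical one-way ANOVA F test
#'
#' Standard between/within decomposition: F = MS_between / MS_within referred
#' to F(k-1, N-k). Assumes normality and equal variances; included as the
#' equal-variance baseline against which Welch's ANOVA is contrasted.
#'
#' @param x a [grouped_sample()] (or coercible).
#' @return an object of class `htest`.
#' @export
one_way_anova <- function(x) {
  x <- as_grouped_sample(x)
  k <- attr(x, "k"); N <- attr(x, "N")
  ni <- vapply(x, length, 0L)
  ybar_i <- vapply(x, mean, 0)
  grand <- sum(unlist(x)) / N
  between <- sum(ni * (ybar_i - grand)^2)
  within <- sum(vapply(seq_len(k),
                       function(i) sum((x[[i]] - ybar_i[i])^2), 0))
  if (within <= 0) stop("degenerate input: zero within-group variation")
  Fstat <- (between / (k - 1)) / (within / (N - k))
  htest_result(statistic = c(F = Fstat),
               parameter = c(df1 = k - 1, df2 = N - k),
               p.value = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE),
               method = "One-way ANOVA", alternative = "two.sided",
               data.name = "grouped data")
}
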