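#' Variance-ratio F test for two groups
#'
#' Tests equality of two population variances for normally distributed data
#' via \eqn{F = (s_x^2 / s_y^2) / \rho_0} referred to F(n_x-1, n_y-1). The
#' alternative is stated for the x group relative to y: `"greater"` means
#' \eqn{\sigma_x^2 > \rho_0 \sigma_y^2}. Sensitive to outliers and
#' non-normality because it works on the raw sample variances.
#'
#' @param x,y numeric vectors, each of length at least 2 with positive
#'   sample variance.
#' @param alternative one of `"two.sided"`, `"less"`, `"greater"`.
#' @param ratio0 hypothesised variance ratio under the null (default 1).
#' @return an object of class `htest`.
#' @export
f_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                   ratio0 = 1) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0)
    stop("degenerate input: zero sample variance in one group")
  f <- (vx / vy) / ratio0
  df1 <- length(x) - 1; df2 <- length(y) - 1
  pl <- stats::pf(f, df1, df2)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(pl, 1 - pl)),
              less = pl,
              greater = 1 - pl)
  htest_result(statistic = c(F = f), parameter = c(df1 = df1, df2 = df2),
               p.value = p, method = "Variance-ratio F test",
               alternative = alternative,
               estimate = c("ratio of variances" = vx / vy),
               data.name = "x and y")
}

#' Welch-Satterthwaite degrees of freedom
#'
#' Moment-matched degrees of freedom for the unequal-variance t statistic:
#' \deqn{df = (s_1^2/n_1 + s_2^2/n_2)^2 /
#'   [(s_1^2/n_1)^2/(n_1-1) + (s_2^2/n_2)^2/(n_2-1)].}
#' Always lies between min(n1,n2)-1 and n1+n2-2.
#'
#' @param s1sq,s2sq sample variances.
#' @param n1,n2 group sizes, each at least 2.
#' @return degrees of freedom (real).
#' @export
welch_df <- function(s1sq, s2sq, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("need n1, n2 >= 2")
  if (s1sq < 0 || s2sq < 0) stop("variances must be nonnegative")
  if (s1sq == 0 && s2sq == 0) stop("degenerate input: both variances zero")
  a <- s1sq / n1; b <- s2sq / n2
  (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
}

#' Two-sample t test for means, pooled or Welch
#'
#' The classical location test in both flavours: `var.equal = TRUE` pools the
#' two sample variances and refers to t(n1+n2-2); `var.equal = FALSE` (Welch)
#' uses the per-group variances with [welch_df()] degrees of freedom. With
#' equal group sizes the two statistics coincide and only the reference
#' degrees of freedom differ, which is exactly the contrast driving the
#' false-rejection inflation this package's simulations quantify when
#' variances are unequal but a pooled test is used.
#'
#' @param x,y numeric vectors.
#' @param var.equal assume equal variances (pooled) or not (Welch).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (mean of x
#'   relative to mean of y).
#' @param mu hypothesised mean difference.
#' @return an object of class `htest`.
#' @export
welch_t_test <- function(x, y, var.equal = FALSE,
                         alternative = c("two.sided", "less", "greater"),
                         mu = 0) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var.equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) stop("degenerate input: zero pooled variance")
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t test (pooled variance)"
  } else {
    if (v1 == 0 && v2 == 0) stop("degenerate input: both variances zero")
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- welch_df(v1, v2, n1, n2)
    method <- "Welch two-sample t test"
  }
  tstat <- (mean(x) - mean(y) - mu) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              less = stats::pt(tstat, df),
              greater = stats::pt(tstat, df, lower.tail = FALSE))
  htest_result(statistic = c(t = tstat), parameter = c(df = df), p.value = p,
               method = method, alternative = alternative,
               estimate = c("difference of means" = mean(x) - mean(y)),
               data.name = "x and y")
}

#' Walsh means of a sample
#'
#' The n(n+1)/2 pairwise averages \eqn{(Y_a + Y_b)/2} over all pairs a <= b
#' (each observation paired with itself included). Their median is a robust
#' location estimate used to align group medians before the Ansari-Bradley
#' test.
#'
#' @param x numeric vector.
#' @return numeric vector of length `length(x) * (length(x) + 1) / 2`.
#' @export
walsh_means <- function(x) {
  n <- length(x)
  if (n < 1) stop("need at least one observation")
  m <- outer(x, x, "+") / 2
  m[upper.tri(m, diag = TRUE)]
}

#' Ansari-Bradley test of equal scale
#'
#' Rank test for the null that two samples share the same dispersion, assuming
#' (unless aligned) equal medians. The pooled sample is scored from both ends
#' (see [ansari_scores()]) and W is the score sum of the smaller group; under
#' the null that group's positions are an exchangeable random subset, giving a
#' bell-shaped discrete null for W, enumerated exactly by
#' [ansari_exact_null()]. A more dispersed group occupies extreme positions
#' and drives W down. With unequal medians, setting `align_medians = TRUE`
#' centres each group at the median of its Walsh means before ranking; note
#' that estimating and removing medians is not strictly distribution-free, so
#' a warning is emitted.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @param alternative alternative about the dispersion of x relative to y:
#'   `"greater"` means x is more spread out.
#' @param mode `"exact"`, `"approximate"` (normal), or `"auto"` (exact when
#'   there are no ties and the pooled size is within the exact cap).
#' @param align_medians shift each group to Walsh-median zero before ranking.
#' @return an object of class `htest`; component `scored_group` names the
#'   group whose scores were summed.
#' @export
ansari_bradley_test <- function(x, y,
                                alternative = c("two.sided", "less", "greater"),
                                mode = c("auto", "exact", "approximate"),
                                align_medians = FALSE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 observations")
  if (align_medians) {
    warning("aligning medians via Walsh means: median estimation is not a ",
            "strictly distribution-free step")
    x <- x - stats::median(walsh_means(x))
    y <- y - stats::median(walsh_means(y))
  }
  pooled <- c(x, y)
  N <- length(pooled)
  if (length(unique(pooled)) == 1L)
    stop("degenerate input: all observations identical")
  ties <- anyDuplicated(pooled) > 0L
  # per-observation scores; ties get the average score of their block
  sc_pos <- ansari_scores(N)
  o <- order(pooled)
  sc_sorted <- stats::ave(sc_pos, pooled[o], FUN = mean)
  sc <- numeric(N); sc[o] <- sc_sorted
  # score the smaller group (x when equal)
  score_x <- length(x) <= length(y)
  idx <- if (score_x) seq_along(x) else length(x) + seq_along(y)
  m <- length(idx); n <- N - m
  W <- sum(sc[idx])
  # map user's alternative (about x vs y spread) to the scored group's tail:
  # the scored group being more dispersed pushes W low
  alt_scored <- alternative
  if (!score_x && alternative != "two.sided")
    alt_scored <- if (alternative == "greater") "less" else "greater"

  use_exact <- switch(mode,
                      exact = TRUE,
                      approximate = FALSE,
                      auto = !ties && N <= 200L)
  if (use_exact && ties) {
    warning("ties present: exact null unavailable, using normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    null <- ansari_exact_null(m, n)
    p_low <- sum(null$pmf[null$support <= W + 1e-9])
    p_up <- sum(null$pmf[null$support >= W - 1e-9])
    p <- switch(alt_scored,
                greater = p_low,           # scored group more dispersed: W low
                less = p_up,
                two.sided = min(1, 2 * min(p_low, p_up)))
    ref <- "exact"
  } else {
    # finite-population moments of the (tie-averaged) score sum
    mu <- m * mean(sc)
    v <- m * n / (N - 1) * (mean(sc^2) - mean(sc)^2)
    if (v <= 0) stop("degenerate input: zero score variance")
    z <- (W - mu) / sqrt(v)
    p <- switch(alt_scored,
                greater = stats::pnorm(z),
                less = stats::pnorm(z, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(-abs(z)))
    ref <- "normal approximation"
  }
  htest_result(statistic = c(W = W), p.value = p,
               method = paste0("Ansari-Bradley test (", ref,
                               if (align_medians) ", median-aligned" else "",
                               ")"),
               alternative = alternative,
               data.name = "x and y",
               scored_group = if (score_x) "x" else "y",
               exact = use_exact)
}

#' Moses rank-like test of equal dispersion
#'
#' Dispersion test that, unlike Ansari-Bradley, tolerates unequal and unknown
#' medians. Each group is randomly partitioned into subsets of equal size
#' (leftover observations discarded), the within-subset sum of squared
#' deviations D is computed for every subset, and a Wilcoxon rank-sum test
#' compares the two collections of D's. Because the result depends on the
#' random partition, the partition is redrawn `repartitions` times and the
#' median p-value is reported, along with the spread of p-values across
#' repartitions.
#'
#' @param x,y numeric vectors.
#' @param subset_size size of each subset (default 3).
#' @param repartitions number of random repartitions (default 200).
#' @param alternative alternative about the dispersion of x relative to y.
#' @param seed optional integer seed for the repartition stream.
#' @return an object of class `htest`; components `p_values` (per repartition)
#'   and `p_iqr` report the repartition-to-repartition variability.
#' @export
moses_test <- function(x, y, subset_size = 3, repartitions = 200,
                       alternative = c("two.sided", "less", "greater"),
                       seed = NULL) {
  alternative <- match.arg(alternative)
  if (subset_size < 2) stop("subset_size must be >= 2")
  kx <- floor(length(x) / subset_size)
  ky <- floor(length(y) / subset_size)
  if (kx < 2 || ky < 2)
    stop("each group must yield at least 2 subsets; need n >= ",
         2 * subset_size, " per group")
  if (!is.null(seed)) set.seed(seed)
  subset_ss <- function(v, nsub) {
    idx <- sample(length(v), nsub * subset_size)
    grp <- rep(seq_len(nsub), each = subset_size)
    vapply(split(v[idx], grp),
           function(s) sum((s - mean(s))^2), 0)
  }
  ps <- vapply(seq_len(repartitions), function(r) {
    dx <- subset_ss(x, kx); dy <- subset_ss(y, ky)
    suppressWarnings(stats::wilcox.test(dx, dy,
                                        alternative = alternative)$p.value)
  }, 0)
  htest_result(statistic = c("median p" = stats::median(ps)),
               p.value = stats::median(ps),
               method = sprintf(
                 "Moses rank-like test (subset size %d, %d repartitions)",
                 subset_size, repartitions),
               alternative = alternative, data.name = "x and y",
               p_values = ps, p_iqr = stats::IQR(ps),
               discarded = c(x = length(x) - kx * subset_size,
                             y = length(y) - ky * subset_size))
}

# leave-one-out pseudo-value machinery for one group
jackknife_side <- function(v, label) {
  n <- length(v)
  if (n < 3) stop("jackknife needs group size >= 3 (", label, ")")
  m <- mean(v)
  ss <- sum((v - m)^2)
  loo_ss <- ss - n / (n - 1) * (v - m)^2
  D <- loo_ss / (n - 2)
  if (any(D <= 0)) {
    i <- which(D <= 0)[1]
    stop("degenerate input: leave-one-out variance is zero when dropping ",
         "observation ", i, " of group ", label)
  }
  D0 <- ss / (n - 1)
  if (D0 <= 0) stop("degenerate input: zero variance in group ", label)
  S0 <- log(D0)
  A <- n * S0 - (n - 1) * log(D)
  Abar <- mean(A)
  list(mean = Abar, var_of_mean = sum((A - Abar)^2) / (n * (n - 1)))
}

#' Miller's Jackknife test of equal variances
#'
#' Two-sample scale test built on jackknife pseudo-values of the log sample
#' variance: for each group, leave-one-out variances \eqn{D_{(i)}} give
#' pseudo-values \eqn{A_i = n \ln D_{(0)} - (n-1) \ln D_{(i)}} whose mean and
#' variance-of-mean feed the statistic
#' \eqn{Q = (\bar B - \bar A)/\sqrt{V_A + V_B}}. Under the null Q is
#' approximately standard normal, or more exactly t with n1+n2-2 degrees of
#' freedom. The test needs only finite fourth moments, not normality, and
#' also yields the point estimate \eqn{\hat\gamma^2 = e^{\bar B - \bar A}} of
#' var(y)/var(x).
#'
#' @param x,y numeric vectors, each of length at least 3.
#' @param mode `"exact_t"` (t reference with n1+n2-2 df), `"normal"`, or
#'   `"auto"` (exact_t when n1+n2 < 60).
#' @param alternative alternative about the variance of x relative to y.
#' @return an object of class `htest`; `estimate` holds
#'   \eqn{\hat\gamma^2 = } var(y)/var(x).
#' @export
jackknife_test <- function(x, y, mode = c("auto", "exact_t", "normal"),
                           alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  a <- jackknife_side(x, "x")
  b <- jackknife_side(y, "y")
  Q <- (b$mean - a$mean) / sqrt(a$var_of_mean + b$var_of_mean)
  n1 <- length(x); n2 <- length(y)
  if (mode == "auto") mode <- if (n1 + n2 < 60) "exact_t" else "normal"
  # x more dispersed pushes Q negative
  if (mode == "exact_t") {
    df <- n1 + n2 - 2
    p <- switch(alternative,
                greater = stats::pt(Q, df),
                less = stats::pt(Q, df, lower.tail = FALSE),
                two.sided = 2 * stats::pt(-abs(Q), df))
    par <- c(df = df)
    ref <- sprintf("t(%d) reference", df)
  } else {
    p <- switch(alternative,
                greater = stats::pnorm(Q),
                less = stats::pnorm(Q, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(-abs(Q)))
    par <- NULL
    ref <- "normal reference"
  }
  htest_result(statistic = c(Q = Q), parameter = par, p.value = p,
               method = paste0("Jackknife test of equal variances (", ref, ")"),
               alternative = alternative,
               estimate = c("gamma^2 = var(y)/var(x)" = exp(b$mean - a$mean)),
               data.name = "x and y")
}
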