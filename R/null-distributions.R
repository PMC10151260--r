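#' Ansari-Bradley position scores
#'
#' In the Ansari-Bradley ranking scheme the pooled sample is sorted and the
#' smallest and largest observations both get score 1, the second smallest and
#' second largest score 2, and so on, so extreme positions carry small scores
#' and positions near the median carry large ones. Position j (1-based, sorted
#' order) gets score min(j, N+1-j); the score vector is palindromic and its
#' maximum is ceiling(N/2).
#'
#' @param N pooled sample size, at least 2.
#' @return integer vector of length `N`.
#' @examples
#' ansari_scores(10)  # 1 2 3 4 5 5 4 3 2 1
#' @export
ansari_scores <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  j <- seq_len(N)
  pmin(j, N + 1L - j)
}

# memo cache for exact nulls (keyed "m.n")
.ansari_cache <- new.env(parent = emptyenv())

#' Exact null distribution of the Ansari-Bradley W statistic
#'
#' Under the null of equal dispersion (and equal medians), the m positions
#' occupied by the smaller group are a uniformly random size-m subset of the
#' N = m + n pooled positions, so the null law of W (the sum of the group's
#' Ansari scores) is obtained by counting, for every attainable score sum, the
#' number of size-m subsets achieving it. The count is computed by an exact
#' dynamic-programming convolution over the score vector (polynomial time, no
#' subset enumeration needed).
#'
#' @param m size of the scored (smaller) group, `2 <= m <= n`.
#' @param n size of the other group.
#' @return an object of class `exact_null`: list with `support` (sorted
#'   attainable W values), `pmf`, `mean`, `variance`, `m`, `n`.
#' @export
ansari_exact_null <- function(m, n) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 2L || n < m) stop("need 2 <= m <= n")
  if (m + n > 200L)
    stop("m + n = ", m + n, " exceeds the exact cap (200); ",
         "use the large-sample approximation (ansari_large_sample)")
  key <- paste0(m, ".", n)
  if (!is.null(got <- .ansari_cache[[key]])) return(got)
  sc <- ansari_scores(m + n)
  wmax <- sum(sort(sc, decreasing = TRUE)[seq_len(m)])
  # counts[j+1, w+1] = number of subsets of size j with score sum w
  counts <- matrix(0, nrow = m + 1L, ncol = wmax + 1L)
  counts[1L, 1L] <- 1
  for (s in sc) {
    jmax <- m  # process in decreasing j so each score is used at most once
    for (j in seq.int(jmax, 1L)) {
      w <- seq_len(wmax + 1L - s)
      counts[j + 1L, w + s] <- counts[j + 1L, w + s] + counts[j, w]
    }
  }
  cnt <- counts[m + 1L, ]
  keep <- cnt > 0
  support <- which(keep) - 1L
  pmf <- cnt[keep] / sum(cnt[keep])
  mu <- sum(support * pmf)
  out <- structure(list(
    support = support, pmf = pmf,
    mean = mu, variance = sum((support - mu)^2 * pmf),
    m = m, n = n
  ), class = "exact_null")
  .ansari_cache[[key]] <- out
  out
}

#' @export
print.exact_null <- function(x, ...) {
  cat(sprintf("exact null of Ansari-Bradley W (m=%d, n=%d): support [%d, %d], mean %.4g, variance %.4g\n",
              x$m, x$n, min(x$support), max(x$support), x$mean, x$variance))
  invisible(x)
}

#' Exact tail critical values of the Ansari-Bradley W statistic
#'
#' For the upper tail, returns the smallest w with \eqn{P(W \ge w) \le \alpha};
#' for the lower tail the largest w with \eqn{P(W \le w) \le \alpha}. Returns
#' `NA` when no support point attains the bound (the discrete null's most
#' extreme tail mass already exceeds alpha).
#'
#' @param m,n group sizes as in [ansari_exact_null()].
#' @param alpha tail probability, in (0, 0.5].
#' @param tail `"lower"` or `"upper"`.
#' @return an integer critical value, or `NA_integer_`.
#' @export
ansari_critical <- function(m, n, alpha, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 0.5)
    stop("alpha must lie in (0, 0.5]")
  null <- ansari_exact_null(m, n)
  if (tail == "upper") {
    upper <- rev(cumsum(rev(null$pmf)))  # P(W >= support)
    ok <- which(upper <= alpha + 1e-12)
    if (!length(ok)) return(NA_integer_)
    as.integer(null$support[min(ok)])
  } else {
    lower <- cumsum(null$pmf)            # P(W <= support)
    ok <- which(lower <= alpha + 1e-12)
    if (!length(ok)) return(NA_integer_)
    as.integer(null$support[max(ok)])
  }
}

#' Null mean and variance of the Ansari-Bradley W statistic
#'
#' First two moments of W under the null, computed directly from the score
#' vector without enumeration: sampling m scores without replacement from the
#' finite score population gives mean \eqn{m \bar s} and variance
#' \eqn{m n (N \sum s^2 - (\sum s)^2) / (N^2 (N-1))}.
#'
#' @param m,n group sizes (m is the scored group); both at least 2.
#' @return named numeric vector `c(mean, variance)`.
#' @export
ansari_large_sample <- function(m, n) {
  if (m < 2 || n < 2) stop("need m, n >= 2")
  N <- m + n
  s <- ansari_scores(N)
  c(mean = m * sum(s) / N,
    variance = m * n * (N * sum(s^2) - sum(s)^2) / (N^2 * (N - 1)))
}

#' CDF of Hartley's Fmax statistic
#'
#' Distribution of the ratio of the largest to the smallest of k independent
#' sample variances, each on `df` degrees of freedom, under variance
#' homogeneity. Computed by numerical quadrature of
#' \deqn{k \int_0^\infty g(u) [G(cu) - G(u)]^{k-1} du}
#' with g/G the chi-square(df) density/CDF (the scale cancels in the ratio);
#' the probability substitution p = G(u) turns this into a smooth, bounded
#' integral over (0, 1) that stays accurate for arbitrarily large df.
#'
#' @param c ratio value; values below 1 have probability 0.
#' @param k number of groups, at least 2.
#' @param df per-group degrees of freedom (common group size minus 1).
#' @return \eqn{P(F_{max} \le c)}.
#' @export
fmax_cdf <- function(c, k, df) {
  if (k < 2 || df < 1) stop("need k >= 2 and df >= 1")
  if (c <= 1) return(0)
  integrand <- function(p) {
    u <- stats::qchisq(p, df)
    k * (stats::pchisq(c * u, df) - p)^(k - 1)
  }
  stats::integrate(integrand, 0, 1, rel.tol = 1e-9, abs.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' Critical values (quantiles) of Hartley's Fmax distribution
#'
#' Solves \eqn{P(F_{max} \le c) = 1 - \alpha} for c by bracketing and root
#' finding; the bracket starts at [1, 10] and doubles its upper end until the
#' CDF exceeds the target. As df grows the critical value tends to 1 (with
#' infinite data every sample variance equals the true variance).
#'
#' @param alpha upper-tail probability, in (0, 0.5].
#' @param k number of groups.
#' @param df per-group degrees of freedom.
#' @return the critical value c with \eqn{P(F_{max} > c) = \alpha}.
#' @export
fmax_quantile <- function(alpha, k, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 0.5)
    stop("alpha must lie in (0, 0.5]")
  target <- 1 - alpha
  hi <- 10
  while (fmax_cdf(hi, k, df) < target) {
    hi <- hi * 2
    if (hi > 1e12) stop("fmax_quantile failed to bracket the root (alpha=",
                        alpha, ", k=", k, ", df=", df, ")")
  }
  stats::uniroot(function(cc) fmax_cdf(cc, k, df) - target,
                 lower = 1 + 1e-12, upper = hi, tol = 1e-9)$root
}

#' Upper limit for Cochran's C statistic
#'
#' One-sided bound for the largest-variance outlier test: with k groups of
#' common size n, \eqn{C_{UL} = 1 / (1 + (k-1)/F^*)} where \eqn{F^*} is the
#' upper alpha/k quantile of F(n-1, (k-1)(n-1)). The alpha/k divisor is the
#' Bonferroni adjustment for testing the (one) most extreme of k group
#' variances. The bound always exceeds 1/k (the value every C_j takes under
#' exact equality of sample variances).
#'
#' @param alpha test level, in (0, 1).
#' @param n common group size, at least 2.
#' @param k number of groups, at least 2.
#' @return the upper limit, a value in (1/k, 1).
#' @export
cochran_upper_limit <- function(alpha, n, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (n < 2 || k < 2) stop("need n >= 2 and k >= 2")
  fstar <- stats::qf(1 - alpha / k, n - 1, (k - 1) * (n - 1))
  1 / (1 + (k - 1) / fstar)
}

#' Regenerate critical-value tables
#'
#' Emits Ansari-Bradley exact critical values (for given m rows) and Hartley
#' Fmax critical values as data frames, for comparison against published
#' tables.
#'
#' @param m,n_range Ansari-Bradley group sizes: scored group size `m`, range
#'   of the other group's size.
#' @param alphas tail probabilities for the Ansari table.
#' @param k_range,df_range,fmax_alphas grid for the Fmax table.
#' @return list of two data frames, `ansari` and `fmax`.
#' @export
critical_value_tables <- function(m = 5, n_range = m:10,
                                  alphas = c(0.05, 0.025, 0.01, 0.005),
                                  k_range = 2:5, df_range = 2:5,
                                  fmax_alphas = c(0.05, 0.01)) {
  ansari <- do.call(rbind, lapply(n_range, function(n) {
    row <- data.frame(m = m, n = n)
    for (a in alphas) {
      row[[paste0("lower_", a)]] <- ansari_critical(m, n, a, "lower")
      row[[paste0("upper_", a)]] <- ansari_critical(m, n, a, "upper")
    }
    row
  }))
  fmax <- expand.grid(alpha = fmax_alphas, k = k_range, df = df_range)
  fmax$critical <- mapply(fmax_quantile, fmax$alpha, fmax$k, fmax$df)
  list(ansari = ansari, fmax = fmax)
}
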