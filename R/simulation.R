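# Registry of simulation tests. Each entry: a human-readable name, the group
# counts it applies to, and a function grouped_sample, alpha -> reject (logical).
# The two-sample-only tests receive the two groups as vectors.
sim_test_registry <- function() {
  two <- function(fun) function(gs, alpha) fun(gs[[1]], gs[[2]], alpha)
  list(
    f = list(min_k = 2, max_k = 2, fun = two(function(x, y, a)
      f_test(x, y)$p.value < a)),
    bartlett = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      bartlett_test(gs)$p.value < a),
    levene_mean = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      levene_test(gs, "mean")$p.value < a),
    levene_median = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      levene_test(gs, "median")$p.value < a),
    levene_trimmed = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      levene_test(gs, "trimmed")$p.value < a),
    levene_rank = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      levene_test(gs, "rank")$p.value < a),
    fligner = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      fligner_killeen_test(gs)$p.value < a),
    ansari = list(min_k = 2, max_k = 2, fun = two(function(x, y, a)
      ansari_bradley_test(x, y)$p.value < a)),
    ansari_adjusted = list(min_k = 2, max_k = 2, fun = two(function(x, y, a)
      suppressWarnings(
        ansari_bradley_test(x, y, align_medians = TRUE))$p.value < a)),
    jackknife_normal = list(min_k = 2, max_k = 2, fun = two(function(x, y, a)
      jackknife_test(x, y, mode = "normal")$p.value < a)),
    jackknife_exact = list(min_k = 2, max_k = 2, fun = two(function(x, y, a)
      jackknife_test(x, y, mode = "exact_t")$p.value < a)),
    hartley = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      hartley_test(gs, alpha = a)$reject),
    cochran = list(min_k = 2, max_k = Inf, fun = function(gs, a)
      cochran_c_test(gs, alpha = a)$reject)
  )
}

#' Names of the simulation tests available for a given group count
#'
#' The two-sample battery (k = 2) mirrors the 11-test comparison of the power
#' study: F, the four Levene variants, Bartlett, Ansari-Bradley with and
#' without median adjustment, Jackknife (normal and exact-t), and
#' Fligner-Killeen. For k > 2 the applicable subset is the Levene family,
#' Bartlett, Fligner-Killeen, Hartley and Cochran.
#'
#' @param k group count.
#' @param normal_only if `FALSE`, drops the tests whose validity requires
#'   normality (F, Bartlett, Hartley, Cochran).
#' @return character vector of test names.
#' @export
available_tests <- function(k = 2, normal_only = TRUE) {
  reg <- sim_test_registry()
  nm <- names(reg)[vapply(reg, function(e) k >= e$min_k && k <= e$max_k, TRUE)]
  if (!normal_only)
    nm <- setdiff(nm, c("f", "bartlett", "hartley", "cochran"))
  nm
}

#' Estimate rejection proportions for one scenario
#'
#' The Monte-Carlo kernel: for each of `sc$reps` replicates, generates the k
#' groups (seeded per replicate) and records, for every requested test,
#' whether it rejects at `sc$alpha` (p < alpha, or the critical-value decision
#' for Hartley and Cochran). Replicates on which a test raises a
#' degenerate-input error are counted as non-rejections (conservative) and
#' tallied in `n_error`. The whole computation is deterministic for a fixed
#' scenario seed.
#'
#' @param sc a [scenario()].
#' @param tests character vector of test names (see [available_tests()]).
#' @return a data frame with one row per test: scenario_id, family, k, n,
#'   test, reps, alpha, reject_prop, mc_se (binomial
#'   \eqn{\sqrt{\hat p(1-\hat p)/reps}}), n_error.
#' @export
estimate_rejection <- function(sc, tests = available_tests(sc$k)) {
  stopifnot(inherits(sc, "scenario"))
  reg <- sim_test_registry()
  unknown <- setdiff(tests, names(reg))
  if (length(unknown)) stop("unknown test(s): ", paste(unknown, collapse = ", "))
  for (t in tests) {
    e <- reg[[t]]
    if (sc$k < e$min_k || sc$k > e$max_k)
      stop("test '", t, "' is not applicable to k = ", sc$k, " groups")
  }
  rejects <- matrix(FALSE, nrow = sc$reps, ncol = length(tests),
                    dimnames = list(NULL, tests))
  errors <- integer(length(tests)); names(errors) <- tests
  for (r in seq_len(sc$reps)) {
    gs <- make_scenario_groups(sc, r)
    for (t in tests) {
      res <- tryCatch(reg[[t]]$fun(gs, sc$alpha), error = function(e) NA)
      if (is.na(res)) {
        errors[t] <- errors[t] + 1L
        res <- FALSE
      }
      rejects[r, t] <- res
    }
  }
  p <- colMeans(rejects)
  data.frame(scenario_id = sc$id, family = sc$family, k = sc$k, n = sc$n,
             test = tests, reps = sc$reps, alpha = sc$alpha,
             reject_prop = unname(p),
             mc_se = unname(sqrt(p * (1 - p) / sc$reps)),
             n_error = unname(errors),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a power grid over sample sizes and scenarios
#'
#' Evaluates [estimate_rejection()] for every scenario in the grid, re-sizing
#' each scenario to every requested n. The full study design crosses sample
#' sizes 11..100 with variance ratios 1:1.5, 1:2, 1:4, 1:9 (normal and skew
#' normal), t degrees-of-freedom pairs 3:12, 3:6, 3:4 (and triples with the
#' small-df group first), at 2000 replicates; every dimension here is
#' configurable so reduced grids run quickly.
#'
#' @param scenarios a list of [scenario()] objects (one per population cell).
#' @param n_values integer vector of common group sizes to run each cell at.
#' @param tests tests to run; default: all applicable to each scenario's k.
#' @return a data frame (rows from [estimate_rejection()], one block per
#'   scenario x n).
#' @export
run_power_grid <- function(scenarios, n_values = NULL, tests = NULL) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  out <- lapply(scenarios, function(sc) {
    ns <- if (is.null(n_values)) sc$n else n_values
    do.call(rbind, lapply(ns, function(n) {
      sci <- sc; sci$n <- as.integer(n)
      tt <- if (is.null(tests)) available_tests(sci$k) else tests
      estimate_rejection(sci, tt)
    }))
  })
  do.call(rbind, out)
}

#' Run a type-I-error grid (null scenarios)
#'
#' Same engine as [run_power_grid()] but every scenario must be a null (all
#' true variances equal), so the rejection proportion estimates the size of
#' each test. For t-family nulls, all groups share df = 3 in the study design.
#'
#' @inheritParams run_power_grid
#' @return a data frame of estimated sizes.
#' @export
run_type1_grid <- function(scenarios, n_values = NULL, tests = NULL) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  bad <- vapply(scenarios, function(sc) !sc$null, TRUE)
  if (any(bad))
    stop("non-null scenario(s) passed to run_type1_grid: ",
         paste(vapply(scenarios[bad], `[[`, "", "id"), collapse = ", "))
  run_power_grid(scenarios, n_values, tests)
}

#' False-rejection rates of the pooled vs Welch t test under unequal variances
#'
#' Replicates the motivating experiment: two samples of size n from
#' Normal(mean 0, variance 1) and Normal(mean 0, variance 5) - equal means, so
#' any rejection by a location test is a false rejection - tested with the
#' two-sample t test both assuming and not assuming equal variances. With
#' equal group sizes the two modes share the same statistic and differ only in
#' reference degrees of freedom, so the pooled proportion is never below the
#' Welch one. At the original reps = 100 the estimates are noisy by design
#' (MC se about 0.03); use a large `reps` for stable values.
#'
#' @param n per-group sample size.
#' @param reps number of replicates.
#' @param variances the two population variances.
#' @param alpha test level.
#' @param seed seed.
#' @return a data frame with rows `pooled` and `welch`: reject_prop, mc_se.
#' @export
location_type1_experiment <- function(n = 15, reps = 100,
                                      variances = c(1, 5), alpha = 0.05,
                                      seed = 1) {
  sc <- scenario_normal(variances, n = n, reps = reps, alpha = alpha,
                        seed = seed, id = "location_type1")
  rej <- matrix(FALSE, nrow = reps, ncol = 2,
                dimnames = list(NULL, c("pooled", "welch")))
  for (r in seq_len(reps)) {
    gs <- make_scenario_groups(sc, r)
    rej[r, "pooled"] <- welch_t_test(gs[[1]], gs[[2]],
                                     var.equal = TRUE)$p.value < alpha
    rej[r, "welch"] <- welch_t_test(gs[[1]], gs[[2]],
                                    var.equal = FALSE)$p.value < alpha
  }
  p <- colMeans(rej)
  data.frame(mode = colnames(rej), n = n, reps = reps,
             reject_prop = unname(p),
             mc_se = unname(sqrt(p * (1 - p) / reps)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Analytic power of the two-sided variance-ratio F test
#'
#' For two normal samples of sizes n1, n2 with true variance ratio
#' \eqn{\rho = \sigma_x^2/\sigma_y^2}, the sample ratio is \eqn{\rho} times a
#' central F(n1-1, n2-1) variable, so the two-sided power at level alpha is
#' \deqn{P(F > q_{1-\alpha/2}/\rho) + P(F < q_{\alpha/2}/\rho).}
#' Used as the closed-form oracle for the Monte-Carlo power estimates.
#'
#' @param ratio true variance ratio \eqn{\sigma_x^2/\sigma_y^2}.
#' @param n1,n2 group sizes.
#' @param alpha test level.
#' @return the exact rejection probability.
#' @export
f_test_power <- function(ratio, n1, n2, alpha = 0.05) {
  df1 <- n1 - 1; df2 <- n2 - 1
  up <- stats::qf(1 - alpha / 2, df1, df2)
  lo <- stats::qf(alpha / 2, df1, df2)
  stats::pf(up / ratio, df1, df2, lower.tail = FALSE) +
    stats::pf(lo / ratio, df1, df2)
}
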