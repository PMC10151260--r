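# The rule table encodes the simulation study's findings as a deterministic,
# auditable mapping from (group count, distribution shape, sample-size band,
# anticipated variance-ratio band) to a ranked list of tests. Band thresholds:
# n < 30 counts as "small", an anticipated max/min variance ratio <= 2 as
# "small". Every cell carries a one-line rationale.
build_rule_table <- function() {
  r <- function(k, dist, size, ratio, rank, test, why)
    data.frame(k_groups = k, distribution = dist, size_band = size,
               ratio_band = ratio, rank = rank, test = test, rationale = why,
               stringsAsFactors = FALSE)
  rules <- list(
    # --- two groups, normal ---
    r("2", "normal", "large", "large", 1, "f",
      "most powerful for normal data at large n and large ratios"),
    r("2", "normal", "large", "large", 2, "bartlett",
      "near-F power for normal data"),
    r("2", "normal", "large", "small", 1, "f",
      "F retains the edge for small ratios when data are normal"),
    r("2", "normal", "large", "small", 2, "jackknife_exact",
      "jackknife performs surprisingly well even under normality"),
    r("2", "normal", "small", "large", 1, "jackknife_exact",
      "robust power at small n; exact-t reference preferred for small samples"),
    r("2", "normal", "small", "large", 2, "f",
      "parametric power if normality is credible"),
    r("2", "normal", "small", "small", 1, "levene_mean",
      "mean-centred Levene is comparably powerful at small n and small ratios"),
    r("2", "normal", "small", "small", 2, "jackknife_exact",
      "good power, but size inflates somewhat at small n"),
    # --- two groups, heavy tails ---
    r("2", "heavy_tailed", "large", "large", 1, "jackknife_normal",
      "jackknife dominates across heavy-tailed scenarios; F/Bartlett invalid"),
    r("2", "heavy_tailed", "large", "small", 1, "jackknife_normal",
      "best power for small ratios in heavy tails"),
    r("2", "heavy_tailed", "large", "small", 2, "levene_trimmed",
      "trimming removes the heavy tails"),
    r("2", "heavy_tailed", "small", "large", 1, "jackknife_exact",
      "exact-t beats the normal reference at small n; caveat: its size can drift toward 0.08 in heavy tails"),
    r("2", "heavy_tailed", "small", "large", 2, "levene_trimmed",
      "size-safe alternative when the jackknife's error rate is a concern"),
    r("2", "heavy_tailed", "small", "small", 1, "jackknife_exact",
      "exact-t beats the normal reference at small n; caveat: its size can drift toward 0.08 in heavy tails"),
    r("2", "heavy_tailed", "small", "small", 2, "levene_mean",
      "conservative fallback with acceptable power"),
    # --- two groups, skewed ---
    r("2", "skewed", "large", "large", 1, "levene_trimmed",
      "highest rejection rates at large ratio and large n for skewed data"),
    r("2", "skewed", "large", "small", 1, "jackknife_normal",
      "most powerful as ratio shrinks in skewed data"),
    r("2", "skewed", "large", "small", 2, "ansari_adjusted",
      "with median alignment, performs well at small ratios (alignment is not distribution-free)"),
    r("2", "skewed", "small", "large", 1, "jackknife_exact",
      "most powerful at small n for skewed data"),
    r("2", "skewed", "small", "large", 2, "levene_trimmed",
      "trimmed centring handles the skew"),
    r("2", "skewed", "small", "small", 1, "jackknife_exact",
      "most powerful when both n and ratio are small"),
    r("2", "skewed", "small", "small", 2, "ansari_adjusted",
      "median-aligned Ansari-Bradley does well at small ratios"),
    # --- 3+ groups, normal ---
    r("3+", "normal", "large", "large", 1, "cochran",
      "most powerful at detecting one inflated variance in normal groups"),
    r("3+", "normal", "large", "large", 2, "bartlett",
      "strong global test for normal data"),
    r("3+", "normal", "large", "large", 3, "hartley",
      "simple Fmax comparison; competitive at large n"),
    r("3+", "normal", "large", "small", 1, "cochran",
      "retains power for modest ratios"),
    r("3+", "normal", "large", "small", 2, "bartlett",
      "strong global test for normal data"),
    r("3+", "normal", "small", "large", 1, "cochran",
      "highest rejection rate at small n"),
    r("3+", "normal", "small", "large", 2, "levene_mean",
      "comparable power at small n; Hartley loses its advantage here"),
    r("3+", "normal", "small", "small", 1, "levene_mean",
      "preferred as both n and ratio shrink"),
    r("3+", "normal", "small", "small", 2, "cochran",
      "still competitive for one inflated variance"),
    # --- 3+ groups, heavy tails ---
    r("3+", "heavy_tailed", "large", "large", 1, "levene_mean",
      "always the best multi-sample test in heavy tails; Hartley/Cochran invalid"),
    r("3+", "heavy_tailed", "large", "large", 2, "levene_trimmed",
      "use if tail contamination is a concern"),
    r("3+", "heavy_tailed", "large", "small", 1, "levene_mean",
      "best power; the rank-based variant also detects small differences well"),
    r("3+", "heavy_tailed", "large", "small", 2, "levene_rank",
      "non-parametric variant works well for small variance differences"),
    r("3+", "heavy_tailed", "small", "large", 1, "levene_mean",
      "best available power at small n in heavy tails"),
    r("3+", "heavy_tailed", "small", "large", 2, "levene_trimmed",
      "robust alternative"),
    r("3+", "heavy_tailed", "small", "small", 1, "levene_mean",
      "best available power; expect low absolute power here"),
    r("3+", "heavy_tailed", "small", "small", 2, "levene_rank",
      "non-parametric variant for small differences"),
    # --- 3+ groups, skewed ---
    r("3+", "skewed", "large", "large", 1, "levene_trimmed",
      "always the most effective test on skewed multi-sample data"),
    r("3+", "skewed", "large", "small", 1, "levene_trimmed",
      "most effective overall"),
    r("3+", "skewed", "large", "small", 2, "fligner",
      "performs fairly well at detecting small variance ratios in skewed data"),
    r("3+", "skewed", "small", "large", 1, "levene_trimmed",
      "most effective overall"),
    r("3+", "skewed", "small", "large", 2, "levene_median",
      "median centring has the smallest error rates in skewed data"),
    r("3+", "skewed", "small", "small", 1, "levene_trimmed",
      "most effective overall"),
    r("3+", "skewed", "small", "small", 2, "fligner",
      "good at small ratios; error rates stay controlled")
  )
  do.call(rbind, rules)
}

#' The recommendation rule table
#'
#' Deterministic ranked rules mapping every combination of group count
#' (`"2"`/`"3+"`), distribution shape (`normal`, `heavy_tailed`, `skewed`),
#' sample-size band (`small` = n below 30, `large`) and anticipated
#' variance-ratio band (`small` = max/min ratio at most 2, `large`) to tests,
#' each with a one-line rationale distilled from the package's own power and
#' size simulations.
#'
#' @return a data frame with columns k_groups, distribution, size_band,
#'   ratio_band, rank, test, rationale.
#' @export
recommendation_rules <- function() build_rule_table()

#' Recommend homogeneity-of-variance tests for a study scenario
#'
#' @param k number of treatment groups (2 or more).
#' @param distribution anticipated shape: `"normal"`, `"heavy_tailed"`, or
#'   `"skewed"`.
#' @param n per-group sample size (used to derive the size band), or pass
#'   `size_band` directly.
#' @param ratio anticipated max/min variance ratio (used to derive the ratio
#'   band), or pass `ratio_band` directly.
#' @param size_band `"small"` or `"large"`; overrides `n`.
#' @param ratio_band `"small"` or `"large"`; overrides `ratio`.
#' @return a data frame of ranked recommendations (rank, test, rationale). If
#'   a combination had no dedicated rule, the median-centred Levene test is
#'   returned as a conservative default.
#' @examples
#' recommend(k = 3, distribution = "skewed", n = 25, ratio = 1.5)
#' @export
recommend <- function(k, distribution = c("normal", "heavy_tailed", "skewed"),
                      n = NULL, ratio = NULL,
                      size_band = NULL, ratio_band = NULL) {
  distribution <- match.arg(distribution)
  if (k < 2) stop("k must be at least 2")
  kb <- if (k == 2) "2" else "3+"
  if (is.null(size_band)) {
    if (is.null(n)) stop("supply `n` or `size_band`")
    size_band <- if (n < 30) "small" else "large"
  }
  if (is.null(ratio_band)) {
    if (is.null(ratio)) stop("supply `ratio` or `ratio_band`")
    ratio_band <- if (ratio <= 2) "small" else "large"
  }
  size_band <- match.arg(size_band, c("small", "large"))
  ratio_band <- match.arg(ratio_band, c("small", "large"))
  tab <- recommendation_rules()
  hit <- tab[tab$k_groups == kb & tab$distribution == distribution &
               tab$size_band == size_band & tab$ratio_band == ratio_band, ]
  if (nrow(hit) == 0) {
    hit <- data.frame(k_groups = kb, distribution = distribution,
                      size_band = size_band, ratio_band = ratio_band,
                      rank = 1, test = "levene_median",
                      rationale = "conservative default (no dedicated rule)",
                      stringsAsFactors = FALSE)
  }
  hit <- hit[order(hit$rank), c("rank", "test", "rationale")]
  rownames(hit) <- NULL
  hit
}

#' Run the full battery of applicable homogeneity tests
#'
#' Applies every homogeneity test that fits the data's group count (the
#' two-sample-only tests only when k = 2; Cochran/Hartley only where their
#' design assumptions hold) and renders a report of method, statistic, p-value
#' and conclusion at `alpha`. P-values are raw: no multiplicity correction is
#' applied across the battery. When any homogeneity test rejects, the location
#' analysis to trust is the heteroscedasticity-robust one, so the report
#' always appends both the equal-variance location test (pooled t / ANOVA) and
#' its Welch counterpart for contrast.
#'
#' @param x a [grouped_sample()] (or coercible).
#' @param alpha level used for the per-test conclusions.
#' @return an object of class `homovar_battery`: list with `homogeneity` (data
#'   frame), `location` (data frame), `any_reject`, `alpha`.
#' @export
battery <- function(x, alpha = 0.05) {
  x <- as_grouped_sample(x)
  k <- attr(x, "k")
  runs <- list(
    `F test` = if (k == 2) function() f_test(x[[1]], x[[2]]),
    `Ansari-Bradley` = if (k == 2)
      function() ansari_bradley_test(x[[1]], x[[2]]),
    `Ansari-Bradley (median-aligned)` = if (k == 2)
      function() suppressWarnings(
        ansari_bradley_test(x[[1]], x[[2]], align_medians = TRUE)),
    `Moses rank-like` = if (k == 2)
      function() moses_test(x[[1]], x[[2]], seed = 1),
    `Jackknife` = if (k == 2) function() jackknife_test(x[[1]], x[[2]]),
    `Levene (mean)` = function() levene_test(x, "mean"),
    `Brown-Forsythe (median)` = function() levene_test(x, "median"),
    `Levene (trimmed mean)` = function() levene_test(x, "trimmed"),
    `Levene (rank)` = function() levene_test(x, "rank"),
    `Bartlett` = function() bartlett_test(x),
    `Hartley Fmax` = function() hartley_test(x, alpha),
    `Cochran C` = function() cochran_c_test(x, alpha),
    `Fligner-Killeen` = function() fligner_killeen_test(x)
  )
  rows <- lapply(names(runs), function(nm) {
    f <- runs[[nm]]
    if (is.null(f))
      return(data.frame(test = nm, statistic = NA_real_, p_value = NA_real_,
                        conclusion = "not applicable (needs 2 groups)",
                        stringsAsFactors = FALSE))
    h <- tryCatch(f(), error = function(e)
      conditionMessage(e))
    if (is.character(h))
      return(data.frame(test = nm, statistic = NA_real_, p_value = NA_real_,
                        conclusion = paste0("not applicable (", h, ")"),
                        stringsAsFactors = FALSE))
    rej <- if (!is.null(h$reject)) h$reject else h$p.value < alpha
    data.frame(test = nm, statistic = unname(h$statistic),
               p_value = if (is.null(h$p.value)) NA_real_ else h$p.value,
               conclusion = if (isTRUE(rej))
                 "variances not all equal" else
                 "cannot reject equal-variance null",
               stringsAsFactors = FALSE)
  })
  hom <- do.call(rbind, rows)
  any_reject <- any(grepl("not all equal", hom$conclusion))
  loc <- if (k == 2) {
    rbind(
      cbind(data.frame(analysis = "pooled t test"),
            results_table(welch_t_test(x[[1]], x[[2]], var.equal = TRUE))),
      cbind(data.frame(analysis = "Welch t test"),
            results_table(welch_t_test(x[[1]], x[[2]], var.equal = FALSE)))
    )
  } else {
    rbind(
      cbind(data.frame(analysis = "one-way ANOVA"),
            results_table(one_way_anova(x))),
      cbind(data.frame(analysis = "Welch ANOVA"),
            results_table(welch_anova(x)))
    )
  }
  structure(list(homogeneity = hom, location = loc,
                 any_reject = any_reject, alpha = alpha, k = k),
            class = "homovar_battery")
}

#' @export
print.homovar_battery <- function(x, ...) {
  cat("Homogeneity-of-variance battery (alpha =", x$alpha, ")\n")
  cat("Note: raw p-values, no multiplicity correction across tests.\n\n")
  print(x$homogeneity, row.names = FALSE)
  cat("\nLocation analysis",
      if (x$any_reject)
        "(heterogeneity detected: trust the Welch row):\n"
      else "(no heterogeneity detected: the equal-variance row applies):\n")
  print(x$location, row.names = FALSE)
  invisible(x)
}
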