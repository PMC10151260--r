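#' Grouped observations for variance-homogeneity testing
#'
#' A `grouped_sample` holds k labeled groups of numeric observations
#' \eqn{Y_{ij}}, the basic data structure every homogeneity test in this
#' package consumes. Groups are kept in first-appearance order; ordering only
#' affects labeling, never any statistic.
#'
#' @param values either a list of numeric vectors (one per group) or a single
#'   numeric vector accompanied by `groups`.
#' @param groups group labels, parallel to `values` when `values` is a vector;
#'   ignored when `values` is a list (names of the list are used, or `g1..gk`).
#' @return An object of class `grouped_sample`: a named list of numeric
#'   vectors with attributes `k` (group count) and `N` (total size).
#' @examples
#' gs <- grouped_sample(list(a = c(1, 2, 3), b = c(2, 4, 6)))
#' summarize_groups(gs)
#' @export
grouped_sample <- function(values, groups = NULL) {
  if (!is.list(values)) {
    if (is.null(groups)) stop("`groups` is required when `values` is a vector")
    if (length(groups) != length(values))
      stop("`values` and `groups` must have equal length")
    lev <- unique(as.character(groups))
    values <- split(as.numeric(values), factor(as.character(groups), levels = lev))
  }
  if (is.null(names(values)) || any(!nzchar(names(values))))
    names(values) <- paste0("g", seq_along(values))
  values <- lapply(values, as.numeric)
  k <- length(values)
  if (k < 2L) stop("need at least 2 groups, got ", k)
  sizes <- vapply(values, length, 0L)
  bad <- names(values)[sizes < 2L]
  if (length(bad))
    stop("every group needs at least 2 observations; offending group(s): ",
         paste(bad, collapse = ", "))
  if (!all(vapply(values, function(v) all(is.finite(v)), TRUE)))
    stop("all observations must be finite numbers")
  structure(values, k = k, N = sum(sizes), class = "grouped_sample")
}

#' @export
print.grouped_sample <- function(x, ...) {
  cat("grouped_sample:", attr(x, "k"), "groups, N =", attr(x, "N"), "\n")
  for (g in names(x))
    cat(sprintf("  %s (n=%d): %s%s\n", g, length(x[[g]]),
                paste(signif(utils::head(x[[g]], 6), 4), collapse = ", "),
                if (length(x[[g]]) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
as.data.frame.grouped_sample <- function(x, ...) {
  data.frame(
    group = rep(names(x), vapply(x, length, 0L)),
    value = unlist(x, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Coerce to a grouped sample
#'
#' @param x a `grouped_sample`, a list of numeric vectors, or a data frame
#'   with a group column and a value column.
#' @param value_col,group_col column names used when `x` is a data frame.
#' @return a `grouped_sample`.
#' @export
as_grouped_sample <- function(x, value_col = "value", group_col = "group") {
  if (inherits(x, "grouped_sample")) return(x)
  if (is.data.frame(x)) {
    for (cl in c(value_col, group_col))
      if (!cl %in% names(x))
        stop("column '", cl, "' not found in the input table")
    return(grouped_sample(x[[value_col]], x[[group_col]]))
  }
  grouped_sample(x)
}

#' Read grouped observations from a long-format delimited table
#'
#' Reads a CSV/TSV file with one group-label column and one numeric-response
#' column. Rows with a missing value or missing group label are dropped (and
#' the drop count reported via a message); values are never imputed.
#'
#' @param path file path; `.tsv`/`.txt` extensions are read tab-separated,
#'   everything else comma-separated, unless `sep` is given.
#' @param value_col,group_col names of the response and group columns.
#' @param sep field separator override.
#' @return a [grouped_sample()].
#' @export
read_grouped_table <- function(path, value_col = "value", group_col = "group",
                               sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c(value_col, group_col))
    if (!cl %in% names(df)) stop("column '", cl, "' not found in ", path)
  val <- suppressWarnings(as.numeric(df[[value_col]]))
  grp <- as.character(df[[group_col]])
  keep <- !is.na(val) & !is.na(grp) & nzchar(grp)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_grouped_table: dropped ", n_drop,
            " row(s) with missing value or group")
  grouped_sample(val[keep], grp[keep])
}

#' Write a grouped sample as a long-format CSV
#'
#' @param x a `grouped_sample`.
#' @param path output file path.
#' @param value_col,group_col column names to write.
#' @return `path`, invisibly.
#' @export
write_grouped_table <- function(x, path, value_col = "value",
                                group_col = "group") {
  df <- as.data.frame(x)
  names(df) <- c(group_col, value_col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-group and pooled summaries
#'
#' Computes, for each group, the sample mean, the unbiased (n-1 denominator)
#' sample variance, and the median, together with the overall mean and the
#' pooled variance \eqn{s_p^2 = \sum_i (n_i - 1) s_i^2 / (N - k)}.
#'
#' @param x a `grouped_sample` (or coercible).
#' @return a list of class `group_summary` with elements `table` (a data
#'   frame: group, n, mean, variance, median), `grand_mean`, `pooled_variance`,
#'   `k`, `N`.
#' @export
summarize_groups <- function(x) {
  x <- as_grouped_sample(x)
  tab <- data.frame(
    group = names(x),
    n = vapply(x, length, 0L),
    mean = vapply(x, mean, 0),
    variance = vapply(x, stats::var, 0),
    median = vapply(x, stats::median, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  N <- attr(x, "N"); k <- attr(x, "k")
  structure(list(
    table = tab,
    grand_mean = sum(unlist(x)) / N,
    pooled_variance = sum((tab$n - 1) * tab$variance) / (N - k),
    k = k, N = N
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("grand mean %.6g, pooled variance %.6g (k=%d, N=%d)\n",
              x$grand_mean, x$pooled_variance, x$k, x$N))
  invisible(x)
}

#' Collect htest results into a flat table
#'
#' @param results a list of `htest` objects (or a single one).
#' @return a data frame with columns method, statistic, df, p_value,
#'   alternative.
#' @export
results_table <- function(results) {
  if (inherits(results, "htest")) results <- list(results)
  do.call(rbind, lapply(results, function(h) {
    df <- if (is.null(h$parameter)) NA_character_ else
      paste(signif(unname(h$parameter), 6), collapse = ";")
    data.frame(
      method = h$method,
      statistic = if (is.null(h$statistic)) NA_real_ else unname(h$statistic),
      df = df,
      p_value = if (is.null(h$p.value)) NA_real_ else h$p.value,
      alternative = if (is.null(h$alternative)) NA_character_ else h$alternative,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write test results to CSV or JSON
#'
#' @param results a list of `htest` objects or a data frame from
#'   [results_table()].
#' @param path output path; format chosen by extension unless `format` given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = NULL) {
  tab <- if (is.data.frame(results)) results else results_table(results)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

# internal: build an htest-style result uniformly
htest_result <- function(statistic, parameter = NULL, p.value = NULL,
                         method, alternative = NULL, estimate = NULL,
                         data.name = "grouped data", ...) {
  out <- c(list(statistic = statistic, parameter = parameter,
                p.value = p.value, method = method,
                alternative = alternative, estimate = estimate,
                data.name = data.name), list(...))
  out <- out[!vapply(out, is.null, TRUE)]
  class(out) <- "htest"
  out
}
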