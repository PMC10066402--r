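#' Per-group summary of a cohort variable
#'
#' @param cohort Cohort data frame.
#' @param variable Name of a numeric column.
#' @param group Name of a two-level grouping column (default `"sex"`).
#' @return Tibble with one row per group: `group`, `n`, `mean`, `sd`.
#'   Missing values are excluded per variable.
#' @export
summarize_by_group <- function(cohort, variable, group = "sex") {
  if (!variable %in% names(cohort)) {
    abort(sprintf("no column '%s' in cohort", variable))
  }
  g <- cohort[[group]]
  g <- if (is.factor(g)) g else factor(g)  # keep declared (possibly empty) levels
  if (nlevels(g) != 2) abort("grouping column must have exactly two levels")
  out <- purrr::map_dfr(levels(g), function(lv) {
    v <- cohort[[variable]][g == lv & !is.na(cohort[[variable]])]
    if (length(v) == 0) abort(sprintf("group '%s' is empty", lv))
    if (length(v) < 2) {
      abort(sprintf("group '%s' has fewer than 2 observations", lv))
    }
    tibble::tibble(group = lv, n = length(v), mean = mean(v),
                   sd = stats::sd(v))
  })
  out$variable <- variable
  out[, c("variable", "group", "n", "mean", "sd")]
}

#' Welch's two-sample t test from summary statistics
#'
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch–Satterthwaite degrees of freedom and a two-sided p value. Computable
#' directly from printed group means, SDs and sizes, as needed to reproduce
#' published cohort tables.
#'
#' @param mean1,sd1,n1 First group's mean, sd, size.
#' @param mean2,sd2,n2 Second group's mean, sd, size.
#' @return Tibble with `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) abort("both group variances are zero")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohort-table style group comparison
#'
#' For each variable: per-group mean/sd/n plus a two-sample t test
#' (Welch's, which agrees with the pooled test to printed precision when
#' variances are similar).
#'
#' @param cohort Cohort data frame.
#' @param variables Character vector of numeric columns to compare.
#' @param group Two-level grouping column (default `"sex"`).
#' @return Tibble with one row per variable: group means/sds/ns, `t`, `df`,
#'   `p`.
#' @export
compare_groups <- function(cohort, variables, group = "sex") {
  purrr::map_dfr(variables, function(v) {
    s <- summarize_by_group(cohort, v, group)
    w <- welch_t(s$mean[1], s$sd[1], s$n[1], s$mean[2], s$sd[2], s$n[2])
    tibble::tibble(
      variable = v,
      group1 = s$group[1], mean1 = s$mean[1], sd1 = s$sd[1], n1 = s$n[1],
      group2 = s$group[2], mean2 = s$mean[2], sd2 = s$sd[2], n2 = s$n[2],
      t = w$t, df = w$df, p = w$p
    )
  })
}
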