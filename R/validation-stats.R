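# Agreement and association statistics: two-way random-effects ICC,
# Bland-Altman limits of agreement, Mann-Whitney, chi-square, Fisher's
# exact, and the stratified clinical comparison report.

#' Paired observer measurements
#'
#' @param sample_id Sample identifiers.
#' @param observer_a,observer_b Numeric measurements in the same units
#'   (e.g., area-fraction percent), no missing pairs, length >= 2.
#' @return A tibble of class `paired_measurements`.
#' @export
paired_measurements <- function(sample_id, observer_a, observer_b) {
  stopifnot(
    length(observer_a) == length(observer_b),
    length(sample_id) == length(observer_a),
    length(observer_a) >= 2,
    !anyNA(observer_a), !anyNA(observer_b)
  )
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    observer_a = as.numeric(observer_a),
    observer_b = as.numeric(observer_b)
  )
  class(out) <- c("paired_measurements", class(out))
  out
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measurement ICC from the two-way ANOVA mean
#' squares (rows = subjects, columns = raters, k = 2):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#'
#' @param pairs A [paired_measurements()] with n >= 3 pairs.
#' @return A list of class `icc_result`: `icc`, `icc_model`, and the mean
#'   squares `ms = c(MSR, MSC, MSE)` with `n`, `k`.
#' @export
icc_two_way <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements") || is.data.frame(pairs))
  x <- cbind(pairs$observer_a, pairs$observer_b)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3) stop("at least 3 pairs required")
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-24) stop("zero total variance")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(
    list(
      icc = icc,
      icc_model = "ICC(2,1): two-way random effects, absolute agreement, single measurement",
      ms = c(MSR = msr, MSC = msc, MSE = mse),
      n = n, k = k
    ),
    class = "icc_result"
  )
}

#' Bland-Altman agreement analysis
#'
#' Per-pair difference (`observer_a - observer_b`) against average, mean
#' difference (bias), and 95% limits of agreement
#' `mean_diff +/- 1.96 * SD(differences)`.
#'
#' @param pairs A [paired_measurements()].
#' @return A list of class `agreement_report`: `ba_mean_diff`, `ba_lower`,
#'   `ba_upper`, `sd_diff`, and a tidy `points` tibble (`sample_id`,
#'   `average`, `difference`) suitable for plotting.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$observer_a - pairs$observer_b
  avg <- (pairs$observer_a + pairs$observer_b) / 2
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      ba_mean_diff = m,
      ba_lower = m - 1.96 * s,
      ba_upper = m + 1.96 * s,
      sd_diff = s,
      points = tibble::tibble(
        sample_id = pairs$sample_id, average = avg, difference = d
      )
    ),
    class = "agreement_report"
  )
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when the combined sample size is <= 12 and there are
#' no ties; tie-corrected normal approximation otherwise.
#'
#' @param group1,group2 Numeric vectors, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return A list: `statistic` (U for group1), `p_value`, `method`.
#' @export
mann_whitney <- function(group1, group2, alternative = "two.sided") {
  if (length(group1) < 1 || length(group2) < 1) stop("both groups must be non-empty")
  n <- length(group1) + length(group2)
  ties <- anyDuplicated(c(group1, group2)) > 0
  exact <- n <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    group1, group2,
    alternative = alternative,
    exact = exact, correct = FALSE
  ))
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation (tie-corrected)"
  )
}

check_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != c(2L, 2L))) stop("a 2x2 table is required")
  if (any(table < 0)) stop("cells must be nonnegative")
  if (any(table != round(table))) stop("cells must be integer counts")
  invisible(table)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1. Requires all expected counts to
#' be positive.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return A list: `statistic`, `p_value`, `df`, `expected`.
#' @export
chi_square_2x2 <- function(table) {
  check_2x2(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("all expected counts must be > 0")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(
    statistic = unname(ct$statistic),
    p_value = ct$p.value,
    df = unname(ct$parameter),
    expected = expected
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by the minimum-likelihood rule (hypergeometric tail
#' summation).
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return A list: `odds_ratio` (conditional MLE), `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  check_2x2(table)
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

summarize_continuous <- function(v) {
  sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
}

summarize_binary <- function(v) sprintf("%.1f%%", 100 * mean(v))

#' Stratified clinical comparison report
#'
#' One row per clinical variable, comparing the B cell-poor and B cell-rich
#' strata of a gradable cohort. Continuous variables use the Mann-Whitney
#' test; binary variables use Fisher's exact test when any expected cell
#' count is below 5 and the chi-square test otherwise. P values are
#' unadjusted. Strata with fewer than 2 patients have their tests skipped
#' and flagged.
#'
#' @param cohort A `cohort_table` from [generate_cohort()], or any data
#'   frame with a `b_cell_status` column (`"poor"`/`"rich"`/`"ungraded"`)
#'   and clinical variable columns.
#' @param variables Variables to compare; defaults to all numeric/logical
#'   columns other than identifiers and status.
#' @return A tibble with `variable`, `summary_poor`, `summary_rich`,
#'   `test`, `statistic`, `p_value`, `flag`.
#' @export
cohort_report <- function(cohort, variables = NULL) {
  stopifnot("b_cell_status" %in% names(cohort))
  graded <- cohort[cohort$b_cell_status %in% c("poor", "rich"), , drop = FALSE]
  if (is.null(variables)) {
    drop <- c("patient_id", "sample_id", "gradable", "b_cell_status")
    variables <- setdiff(names(cohort)[vapply(cohort, function(v)
      is.numeric(v) || is.logical(v), logical(1))], drop)
  }
  rows <- lapply(variables, function(nm) {
    v <- graded[[nm]]
    poor <- v[graded$b_cell_status == "poor"]
    rich <- v[graded$b_cell_status == "rich"]
    binary <- is.logical(v) || all(v %in% c(0, 1))
    summarize <- if (binary) summarize_binary else summarize_continuous
    small <- length(poor) < 2 || length(rich) < 2
    if (small) {
      return(tibble::tibble(
        variable = nm,
        summary_poor = if (length(poor)) summarize(poor) else NA_character_,
        summary_rich = if (length(rich)) summarize(rich) else NA_character_,
        test = NA_character_, statistic = NA_real_, p_value = NA_real_,
        flag = "test skipped: stratum with < 2 patients"
      ))
    }
    if (binary) {
      tab <- rbind(
        c(sum(poor == 1), sum(poor == 0)),
        c(sum(rich == 1), sum(rich == 0))
      )
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher_exact_2x2(tab)
        res <- list(test = "Fisher's exact", statistic = ft$odds_ratio,
                    p = ft$p_value)
      } else {
        cs <- chi_square_2x2(tab)
        res <- list(test = "chi-square", statistic = cs$statistic,
                    p = cs$p_value)
      }
    } else {
      mw <- mann_whitney(poor, rich)
      res <- list(test = "Mann-Whitney", statistic = mw$statistic,
                  p = mw$p_value)
    }
    tibble::tibble(
      variable = nm,
      summary_poor = summarize(poor),
      summary_rich = summarize(rich),
      test = res$test, statistic = res$statistic, p_value = res$p,
      flag = NA_character_
    )
  })
  do.call(rbind, rows)
}
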