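#' Generic statistical test report
#'
#' Light-weight container shared by every test in the package: method name,
#' statistic, degrees of freedom, asymptotic p-value and (where applicable)
#' a resampled Monte-Carlo/permutation p-value with its replicate count and
#' seed.
#'
#' @param method Method name.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (scalar or length-2 `(df1, df2)`), or `NULL`.
#' @param p_value Asymptotic p-value, or `NA`.
#' @param p_resampled Resampled p-value, or `NA`.
#' @param n_resamples Number of resamples, or `NA`.
#' @param seed Seed used for resampling, or `NULL`.
#' @param details Optional named list of extras (sums of squares, effects...).
#' @return An object of class `test_report`.
#' @export
test_report <- function(method, statistic, df = NULL, p_value = NA_real_,
                        p_resampled = NA_real_, n_resamples = NA_integer_,
                        seed = NULL, details = list()) {
  for (p in c(p_value, p_resampled)) {
    if (!is.na(p) && (p < 0 || p > 1)) stop_carollia("p-values must be in [0, 1]")
  }
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 p_resampled = unname(p_resampled),
                 n_resamples = n_resamples, seed = seed, details = details),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat("<test_report> ", x$method, "\n", sep = "")
  cat("  statistic = ", format(x$statistic), sep = "")
  if (!is.null(x$df)) {
    cat(", df = ", paste(format(x$df, digits = 6), collapse = ", "), sep = "")
  }
  cat("\n")
  if (!is.na(x$p_value)) cat("  p = ", format.pval(x$p_value), "\n", sep = "")
  if (!is.na(x$p_resampled)) {
    cat("  resampled p = ", format.pval(x$p_resampled), " (",
        x$n_resamples, " resamples)\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.test_report <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic,
             df1 = if (is.null(x$df)) NA_real_ else x$df[1],
             df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
             p_value = x$p_value, p_resampled = x$p_resampled,
             n_resamples = x$n_resamples %||% NA_integer_,
             seed = x$seed %||% NA_integer_)
}

#' Pearson chi-square test with Monte-Carlo p-value
#'
#' Pearson's chi-squared test for count data with the p-value computed by
#' Monte-Carlo simulation (2000 replicates by default, to suit small
#' samples): tables are simulated uniformly over all tables with both
#' margins fixed (Patefield sampling), and the resampled p-value uses the
#' `(1 + b) / (B + 1)` estimator, which is unbiased under the null and never
#' exactly zero. The classical statistic, `(r-1)(c-1)` degrees of freedom
#' and asymptotic p-value are reported alongside.
#'
#' @param tab Non-negative integer matrix (>= 2 rows and columns, no zero
#'   margin).
#' @param n_rep Number of Monte-Carlo replicates (default 2000).
#' @param seed Integer seed for the simulation.
#' @return A [test_report()].
#' @examples
#' pearson_chisq_mc(matrix(c(1, 13, 14, 40), 2, 2), seed = 1)
#' @export
pearson_chisq_mc <- function(tab, n_rep = 2000, seed = NULL) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_carollia("table must have at least 2 rows and 2 columns")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_carollia("table must contain non-negative integer counts")
  }
  if (sum(tab) == 0) stop_carollia("table total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_carollia("zero row or column margin")
  }
  res <- with_seed(seed, suppressWarnings(
    chisq.test(tab, simulate.p.value = TRUE, B = n_rep)))
  stat <- unname(res$statistic)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  test_report("Pearson chi-square (Monte-Carlo p, fixed margins)",
              statistic = stat, df = df,
              p_value = pchisq(stat, df, lower.tail = FALSE),
              p_resampled = unname(res$p.value), n_resamples = n_rep,
              seed = seed,
              details = list(expected = res$expected))
}

#' Logit-transform percentage data
#'
#' Linearizes the sigmoid distribution of percentage data: a constant `c`
#' (default 1, avoiding zero values) is added to the percentage, the result
#' rescaled to a proportion `q`, and `y = ln(q / (1 - q))` returned. Two
#' conventions for the rescaling are exposed, since percentage data can be
#' held on the 0-100 or the 0-1 scale:
#' `"percent"` uses `q = (value + c) / 100`; `"proportion"` uses
#' `q = value + c` directly (with `c` on the proportion scale).
#'
#' @param values Percentages in \[0, 100) (`"percent"`) or proportions in
#'   \[0, 1) (`"proportion"`).
#' @param c Shift constant (default 1 on the percent scale).
#' @param scale `"percent"` (default) or `"proportion"`.
#' @return Numeric vector of logits.
#' @examples
#' logit_transform(0)    # ln(0.01/0.99) = -4.59512
#' @export
logit_transform <- function(values, c = 1, scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  if (any(!is.finite(values))) stop_carollia("values must be finite")
  if (any(values < 0)) stop_carollia("values must be non-negative")
  q <- if (scale == "percent") (values + c) / 100 else values + c
  if (any(q >= 1)) {
    stop_carollia("value + c reaches or exceeds the upper bound; ",
                  "logit undefined (q >= 1)")
  }
  if (any(q <= 0)) stop_carollia("q <= 0; logit undefined")
  log(q / (1 - q))
}

#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk W test (Royston's algorithm as implemented in
#' `stats::shapiro.test`), wrapped into the package's [test_report()] form.
#'
#' @param x Numeric sample with 3 to 5000 non-missing values; constant
#'   vectors are rejected.
#' @return A [test_report()].
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop_carollia("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (var(x) == 0) stop_carollia("constant sample: W undefined")
  res <- shapiro.test(x)
  test_report("Shapiro-Wilk normality test",
              statistic = unname(res$statistic),
              p_value = unname(res$p.value),
              details = list(n = length(x)))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA, reporting the between/within sums
#' of squares, mean squares, F statistic and p-value.
#'
#' @param y Numeric response.
#' @param groups Group labels (>= 2 groups, each non-empty).
#' @return A [test_report()] with `details$table` holding the Df/Sum Sq/Mean
#'   Sq rows.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(y, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_carollia("need at least 2 groups")
  if (any(table(groups) < 1L)) stop_carollia("each group needs >= 1 value")
  if (length(y) - nlevels(groups) < 1L) {
    stop_carollia("no residual degrees of freedom")
  }
  a <- suppressWarnings(anova(lm(y ~ groups)))
  if (a$`Sum Sq`[2] <= 1e-12 * sum(a$`Sum Sq`)) {
    stop_carollia("zero within-group variance: F undefined")
  }
  test_report("One-way ANOVA",
              statistic = a$`F value`[1],
              df = c(a$Df[1], a$Df[2]),
              p_value = a$`Pr(>F)`[1],
              details = list(sum_sq = setNames(a$`Sum Sq`,
                                               c("between", "within")),
                             mean_sq = setNames(a$`Mean Sq`,
                                                c("between", "within"))))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test. The exact null
#' distribution is enumerated when both samples are tie-free and the pooled
#' size is at most 20; otherwise the normal approximation with midranks and
#' (optionally) continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return A [test_report()] with the W statistic.
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
wilcoxon_ranksum <- function(x, y, continuity = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop_carollia("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = continuity))
  test_report(paste0("Wilcoxon rank-sum (",
                     if (exact) "exact" else "normal approximation", ")"),
              statistic = unname(res$statistic),
              p_value = unname(res$p.value),
              details = list(exact = exact, continuity = continuity && !exact))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; adjusted
#' values are capped at 1 and monotone in the raw ordering.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(pvals) {
  p.adjust(pvals, method = "BH")
}
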