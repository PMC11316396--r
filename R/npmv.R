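rank_matrix <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_carollia("data must be numeric")
  apply(data, 2L, rank)  # midranks for ties
}

check_groups <- function(data, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_carollia("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop_carollia("each group needs at least 2 observations")
  }
  if (length(groups) != nrow(as.matrix(data))) {
    stop_carollia("groups length must match the number of rows")
  }
  groups
}

#' Nonparametric relative treatment effects
#'
#' Rank-based relative effects for multivariate group comparisons: for group
#' `i` and variable `v`, the effect is `(mean pooled midrank - 1/2) / N`,
#' i.e. the probability that a randomly chosen observation from group `i`
#' exceeds a randomly chosen observation from the pooled reference
#' distribution. Effects are 0.5 for every group under exchangeability, and
#' their sample-size-weighted mean is exactly 0.5 per variable.
#'
#' @param data Numeric matrix or data frame (observations x variables).
#' @param groups Group labels, one per row (each group >= 2 observations).
#' @return A groups-by-variables matrix of relative effects, class
#'   `relative_effects`, with group sizes in `attr(, "n")`.
#' @examples
#' relative_effects(matrix(1:6), rep(c("a", "b"), each = 3))
#' @export
relative_effects <- function(data, groups) {
  groups <- check_groups(data, groups)
  R <- rank_matrix(data)
  N <- nrow(R)
  eff <- matrix(NA_real_, nlevels(groups), ncol(R),
                dimnames = list(levels(groups),
                                colnames(data) %||%
                                  paste0("V", seq_len(ncol(R)))))
  for (g in levels(groups)) {
    eff[g, ] <- (colMeans(R[groups == g, , drop = FALSE]) - 0.5) / N
  }
  structure(eff, n = table(groups), class = c("relative_effects", "matrix"))
}

#' @export
print.relative_effects <- function(x, ...) {
  cat("Nonparametric relative effects (0.5 = exchangeable):\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

# Between-group sum of squares of pooled ranks, totalled over variables,
# for a matrix of group-label permutations. R is the N x p rank matrix;
# perm_idx is an n_perm x N matrix of row permutations; sizes are the group
# sizes in level order. Returns the n_perm vector of summed between-SS.
between_ss <- function(R, perm_idx, sizes) {
  n_perm <- nrow(perm_idx)
  N <- ncol(perm_idx)
  p <- ncol(R)
  grand <- colMeans(R)
  B <- numeric(n_perm)
  offset <- 0L
  for (ni in sizes) {
    block <- perm_idx[, (offset + 1L):(offset + ni), drop = FALSE]
    for (v in seq_len(p)) {
      gm <- rowSums(matrix(R[block, v], n_perm, ni)) / ni
      B <- B + ni * (gm - grand[v])^2
    }
    offset <- offset + ni
  }
  B
}

#' Nonparametric multivariate ANOVA-type test
#'
#' Global rank-based test for differences between multivariate samples that
#' need not follow normality. Each variable is midranked over the pooled
#' sample; the ANOVA-type statistic is the ratio of the between-group to the
#' within-group mean square of the rank vectors, totalled over variables:
#' `F_A = tr(H) / tr(G)` with `H` the between and `G` the within rank
#' covariance matrix. Its null distribution is approximated by an
#' F distribution with Box-type (two-moment) degrees of freedom
#' `df1 = (a-1) tr(G)^2 / tr(G^2)` and `df2 = (N-a) tr(G)^2 / tr(G^2)`,
#' generally non-integer; the effective numerator dimension shrinks when the
#' variables are correlated. A permutation analog (whole multivariate rows
#' permuted across group labels) is reported alongside and is the
#' recommended p-value at small samples.
#'
#' @param data Numeric matrix or data frame (observations x variables).
#' @param groups Group labels (each group >= 2 observations).
#' @param n_perm Number of label permutations (default 2000; 0 skips the
#'   permutation analog).
#' @param seed Integer seed for the permutations.
#' @return A [test_report()]; `details` carries the [relative_effects()]
#'   matrix and the trace quantities.
#' @export
anova_type_test <- function(data, groups, n_perm = 2000, seed = NULL) {
  groups <- check_groups(data, groups)
  R <- rank_matrix(data)
  N <- nrow(R)
  a <- nlevels(groups)
  sizes <- as.integer(table(groups))
  # order rows by group so permutation blocks are contiguous
  ord <- order(groups)
  R <- R[ord, , drop = FALSE]
  tss <- colSums(sweep(R, 2L, colMeans(R))^2)
  obs_B <- between_ss(R, matrix(seq_len(N), nrow = 1L), sizes)
  tr_h <- obs_B / (a - 1)
  tr_g <- (sum(tss) - obs_B) / (N - a)
  if (tr_g <= 0) stop_carollia("zero within-group rank variance")
  stat <- tr_h / tr_g
  # Box approximation from the full within covariance of the rank vectors
  G <- matrix(0, ncol(R), ncol(R))
  offset <- 0L
  for (ni in sizes) {
    block <- R[(offset + 1L):(offset + ni), , drop = FALSE]
    cen <- sweep(block, 2L, colMeans(block))
    G <- G + crossprod(cen)
    offset <- offset + ni
  }
  G <- G / (N - a)
  ratio <- sum(diag(G))^2 / sum(G * G)
  df1 <- (a - 1) * ratio
  df2 <- (N - a) * ratio
  p_asym <- pf(stat, df1, df2, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    perm_idx <- with_seed(seed, t(replicate(n_perm, sample.int(N))))
    perm_B <- between_ss(R, perm_idx, sizes)
    perm_stat <- (perm_B / (a - 1)) / ((sum(tss) - perm_B) / (N - a))
    p_perm <- (1 + sum(perm_stat >= stat - 1e-12)) / (n_perm + 1)
  }
  eff <- relative_effects(data, groups)
  test_report("Nonparametric multivariate ANOVA-type test",
              statistic = stat, df = c(df1, df2), p_value = p_asym,
              p_resampled = p_perm,
              n_resamples = if (n_perm > 0) n_perm else NA_integer_,
              seed = seed,
              details = list(relative_effects = eff,
                             tr_between = tr_h, tr_within = tr_g))
}
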