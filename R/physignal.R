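k_statistic_terms <- function(tree) {
  C <- ape::vcv(tree)
  Ci <- solve(C)
  n <- nrow(C)
  one <- rep(1, n)
  s_ci <- sum(Ci)
  expected <- (sum(diag(C)) - n / s_ci) / (n - 1)
  list(C = C, Ci = Ci, n = n, s_ci = s_ci, expected_ratio = expected,
       species = rownames(C))
}

k_statistic <- function(x, terms) {
  r <- x - sum(terms$Ci %*% x) / terms$s_ci   # phylogenetic GLS mean removed
  mse0 <- sum(r^2) / (terms$n - 1)
  mse <- drop(crossprod(r, terms$Ci %*% r)) / (terms$n - 1)
  (mse0 / mse) / terms$expected_ratio
}

#' Blomberg's K phylogenetic signal
#'
#' Ratio-based measure of phylogenetic signal for a continuous trait:
#' the observed ratio of the mean squared error of the tip data (about the
#' phylogenetically corrected mean) to the mean squared error computed under
#' the tree's variance-covariance structure, scaled by its expectation under
#' Brownian motion on the same tree. K = 1 is expected for a Brownian trait;
#' K near 0 indicates no signal. Significance is assessed by permuting trait
#' values across the tips: `p = (1 + #[K_perm >= K_obs]) / (n_perm + 1)`.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param trait Named numeric vector; names must match the tip labels.
#' @param n_perm Number of tip permutations (default 999).
#' @param seed Integer seed.
#' @return A [test_report()] with K as the statistic and the permutation
#'   p-value in `p_resampled`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  if (!inherits(tree, "phylo")) stop_carollia("tree must be a phylo object")
  if (is.null(names(trait))) stop_carollia("trait must be named by species")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    stop_carollia("trait missing for tip(s): ",
                  paste(head(missing, 3), collapse = ", "))
  }
  trait <- trait[tree$tip.label]
  if (anyNA(trait)) stop_carollia("trait contains missing values")
  if (var(trait) == 0) stop_carollia("constant trait: K undefined")
  terms <- k_statistic_terms(tree)
  x <- trait[terms$species]
  k_obs <- k_statistic(x, terms)
  p_perm <- NA_real_
  if (n_perm > 0) {
    k_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      k_statistic(sample(x), terms), numeric(1)))
    p_perm <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  }
  test_report("Blomberg's K (permutation test)", statistic = k_obs,
              p_resampled = p_perm,
              n_resamples = if (n_perm > 0) n_perm else NA_integer_,
              seed = seed,
              details = list(n_tips = terms$n))
}
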