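voc_compound_cols <- function(m) {
  setdiff(names(m), c("species", "ecotype"))
}

check_voc_matrix <- function(m) {
  if (!all(c("species", "ecotype") %in% names(m))) {
    stop_carollia("VOC matrix needs `species` and `ecotype` columns")
  }
  if (anyDuplicated(m$species)) stop_carollia("duplicate species labels")
  comp <- voc_compound_cols(m)
  if (anyDuplicated(comp)) stop_carollia("duplicate compound labels")
  vals <- as.matrix(m[comp])
  if (any(vals < 0)) stop_carollia("negative emission values")
  invisible(m)
}

#' Drop rare VOCs from an emission matrix
#'
#' Removes compounds present (emission strictly positive) in fewer than
#' `min_samples` species, mirroring the pre-filtering applied to compiled
#' fruit-scent datasets where rare peaks and contaminants are discarded.
#' Presence is counted at the species level, the analysis unit of the
#' matrix.
#'
#' @param m VOC data frame: `species`, `ecotype`, one numeric column per
#'   compound.
#' @param min_samples Minimum number of species a compound must occur in
#'   (default 5).
#' @return The filtered data frame (row order preserved); dropped compound
#'   names in `attr(, "dropped")`.
#' @export
prevalence_filter <- function(m, min_samples = 5) {
  check_voc_matrix(m)
  comp <- voc_compound_cols(m)
  prev <- colSums(as.matrix(m[comp]) > 0)
  drop <- comp[prev < min_samples]
  out <- m[, !(names(m) %in% drop), drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

#' Per-species top-k compound lists
#'
#' For each species, ranks its compounds by descending emission (ties broken
#' lexicographically by compound label) and keeps the first `k`, truncating
#' at the last nonzero entry: a compound a species does not emit can never be
#' among its most abundant.
#'
#' @param m VOC data frame.
#' @param k List length (default 20).
#' @return Named list (per species) of character vectors of compound labels.
#' @export
top_k_compounds <- function(m, k = 20) {
  check_voc_matrix(m)
  if (k < 1) stop_carollia("k must be >= 1")
  comp <- voc_compound_cols(m)
  out <- lapply(seq_len(nrow(m)), function(i) {
    v <- as.numeric(m[i, comp])
    ord <- order(-v, comp)
    ord <- ord[v[ord] > 0]
    comp[head(ord, k)]
  })
  setNames(out, m$species)
}

#' Most common compounds across species' top-k lists
#'
#' Ranks compounds by prevalence: the number of species whose top-k list
#' contains them. The selection keeps either every compound above a
#' prevalence threshold (`min_prevalence`) or the first `n_target` compounds
#' in (prevalence descending, label ascending) order, which makes boundary
#' ties deterministic.
#'
#' @param topk Output of [top_k_compounds()].
#' @param n_target Target set size (default 15); mutually exclusive with
#'   `min_prevalence`.
#' @param min_prevalence Minimum prevalence to keep a compound.
#' @return A data frame (class `compound_set`) with `compound` and
#'   `prevalence`, ordered by (prevalence desc, label asc).
#' @export
common_compounds <- function(topk, n_target = 15, min_prevalence = NULL) {
  if (!length(topk)) stop_carollia("empty top-k list")
  tab <- table(unlist(topk, use.names = FALSE))
  df <- data.frame(compound = names(tab), prevalence = as.integer(tab))
  df <- df[order(-df$prevalence, df$compound), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(min_prevalence)) {
    df <- df[df$prevalence >= min_prevalence, , drop = FALSE]
  } else {
    df <- head(df, n_target)
  }
  class(df) <- c("compound_set", class(df))
  df
}

#' Build the three chemical analysis datasets
#'
#' From an emission matrix and a selected compound set, builds the three
#' datasets the scent analyses run on: (1) the species-by-common-compound
#' abundance submatrix, (2) total VOC emission per species (row sum over all
#' compounds), and (3) the number of VOCs each species emits (nonzero
#' count).
#'
#' @param m VOC data frame.
#' @param cs A [common_compounds()] result (or character vector of
#'   compounds); all must be columns of `m`.
#' @return A list with `abundance` (data frame `species`, `ecotype`,
#'   compounds), `total_emission` and `n_compounds` (data frames `species`,
#'   `ecotype`, `value`).
#' @export
build_scent_datasets <- function(m, cs) {
  check_voc_matrix(m)
  compounds <- if (inherits(cs, "compound_set")) cs$compound else cs
  missing <- setdiff(compounds, voc_compound_cols(m))
  if (length(missing)) {
    stop_carollia("compound(s) not in matrix: ",
                  paste(head(missing, 3), collapse = ", "))
  }
  all_vals <- as.matrix(m[voc_compound_cols(m)])
  list(abundance = m[, c("species", "ecotype", compounds), drop = FALSE],
       total_emission = data.frame(species = m$species, ecotype = m$ecotype,
                                   value = unname(rowSums(all_vals))),
       n_compounds = data.frame(species = m$species, ecotype = m$ecotype,
                                value = unname(rowSums(all_vals > 0))))
}
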