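#' Focal Piper species reference table
#'
#' The twelve focal *Piper* species with their ecotype (forest/gap) and
#' succession-habitat classification, used to label synthetic event logs.
#'
#' @return A data frame with `piper_species`, `ecotype`, `habitat`.
#' @export
piper_reference <- function() {
  data.frame(
    piper_species = c("P. auritum", "P. colonense", "P. multiplinervium",
                      "P. reticulatum", "P. sancti-felicis", "P. species D",
                      "P. umbricola", "P. cyanophyllum", "P. generalense",
                      "P. nudifolium", "P. paulowniifolium",
                      "P. sublineatum"),
    ecotype = c(rep("gap", 7), rep("forest", 5)),
    habitat = c("early", "mid", "early", "mid", "early", "mid", "early",
                "mid", "mid", "mid", "mid", "mid"))
}

#' Default visitor-intensity table for synthetic event logs
#'
#' Nightly event intensities per (ecotype, visitor taxon, behavior) cell,
#' emulating the observed interaction structure: bats visit and collect
#' fruit at both ecotypes, whereas fruit removal and consumption by non-bat
#' frugivores (tanagers, wasps, ants, opossums) occurs only at gap plants;
#' forest plants see at most non-bat inspections and occasional whole-plant
#' browsing.
#'
#' @return A data frame with columns `ecotype`, `visitor_taxon`, `behavior`
#'   and `rate` (expected events per night across all plants of the ecotype).
#' @export
default_event_rates <- function() {
  rbind(
    data.frame(ecotype = "forest", visitor_taxon = "bat",
               behavior = c("flyby_visit", "inspect_fruit", "remove_fruit"),
               rate = c(0.30, 0.15, 0.30)),
    data.frame(ecotype = "gap", visitor_taxon = "bat",
               behavior = c("flyby_visit", "inspect_fruit", "remove_fruit"),
               rate = c(0.50, 0.20, 0.15)),
    data.frame(ecotype = "gap", visitor_taxon = "tanager",
               behavior = c("remove_fruit", "eat_fruit"),
               rate = c(0.25, 0.10)),
    data.frame(ecotype = "gap", visitor_taxon = "wasp",
               behavior = "eat_fruit", rate = 0.05),
    data.frame(ecotype = "gap", visitor_taxon = "ant",
               behavior = c("inspect_fruit", "eat_fruit"),
               rate = c(0.05, 0.05)),
    data.frame(ecotype = "gap", visitor_taxon = "opossum",
               behavior = "inspect_fruit", rate = 0.03),
    data.frame(ecotype = "forest", visitor_taxon = "mouse",
               behavior = "inspect_fruit", rate = 0.02),
    data.frame(ecotype = "forest", visitor_taxon = "tapir",
               behavior = "whole_plant_consumption", rate = 0.005),
    data.frame(ecotype = "forest", visitor_taxon = "hummingbird",
               behavior = "flyby_visit", rate = 0.02))
}

#' Generate a synthetic camera-trap event log
#'
#' Draws Poisson event counts per (ecotype, visitor taxon, behavior) cell
#' with mean `rate * n_nights`, assigns each event a random focal species of
#' the matching ecotype, and draws timestamps inside the taxon's activity
#' window: bats are nocturnal (17:00-05:00 local), all other visitors
#' diurnal (05:00-17:00).
#'
#' @param rates Intensity table as returned by [default_event_rates()]
#'   (columns `ecotype`, `visitor_taxon`, `behavior`, `rate`; rates >= 0).
#' @param n_nights Number of recording nights.
#' @param start_date First night (date string or `Date`).
#' @param species Species lookup table ([piper_reference()] by default).
#' @param seed Integer seed.
#' @return A validated event data frame (same schema as [load_events()]),
#'   ordered by timestamp.
#' @export
generate_event_log <- function(rates = default_event_rates(), n_nights = 30,
                               start_date = "2019-06-01",
                               species = piper_reference(), seed = NULL) {
  stopifnot(all(c("ecotype", "visitor_taxon", "behavior", "rate") %in%
                  names(rates)))
  if (any(rates$rate < 0)) stop_carollia("rates must be >= 0")
  start_date <- as.Date(start_date)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(rates)), function(i) {
      r <- rates[i, ]
      n <- rpois(1L, r$rate * n_nights)
      if (n == 0L) return(NULL)
      sp_pool <- species[species$ecotype == r$ecotype, , drop = FALSE]
      sp <- sp_pool[sample.int(nrow(sp_pool), n, replace = TRUE), ]
      night <- sample.int(n_nights, n, replace = TRUE) - 1L
      nocturnal <- is_bat(r$visitor_taxon)
      # offset in seconds from 17:00 (nocturnal) or 05:00 (diurnal)
      off <- runif(n, 0, 12 * 3600)
      base <- as.POSIXct(paste(start_date + night,
                               if (nocturnal) "17:00:00" else "05:00:00"),
                         tz = "")
      data.frame(plant_id = paste0(gsub("[ .]", "_", sp$piper_species), "_1"),
                 piper_species = sp$piper_species,
                 ecotype = sp$ecotype, habitat = sp$habitat,
                 visitor_taxon = r$visitor_taxon, behavior = r$behavior,
                 timestamp = base + off)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(plant_id = character(), piper_species = character(),
                        ecotype = character(), habitat = character(),
                        visitor_taxon = character(), behavior = character(),
                        timestamp = as.POSIXct(character()))
    }
    out[order(out$timestamp), , drop = FALSE]
  })
}

#' Generate a synthetic Carollia diet table
#'
#' Per-species percentages of each *Piper* species in the annual diet of the
#' three *Carollia* species, with a designed ecotype effect: before noise,
#' gap species exceed forest species by `effect_size` percentage points
#' (baseline 0.7%, the scale of observed forest-species diet shares). A
#' per-species random effect shared across the three bat species is added on
#' top of independent noise; values are truncated to \[0, 95\].
#'
#' Defaults follow the compiled diet dataset: 33 *Piper* species, 24 forest
#' and 9 gap, with gap species roughly ten percentage points higher.
#'
#' @param n_forest,n_gap Number of forest and gap species (>= 2 each).
#' @param effect_size Gap-minus-forest mean difference in percentage points.
#' @param noise_sd Noise standard deviation (percentage points).
#' @param seed Integer seed.
#' @return A data frame with `piper_species`, `ecotype`, `habitat` (gap ->
#'   early; forest split mid/late), one percentage column per *Carollia*
#'   species, and `max_pct` / `avg_pct` summaries.
#' @export
generate_diet_table <- function(n_forest = 24, n_gap = 9, effect_size = 10,
                                noise_sd = 3, seed = NULL) {
  if (n_forest < 2 || n_gap < 2) stop_carollia("need >= 2 species per ecotype")
  n <- n_forest + n_gap
  ecotype <- c(rep("forest", n_forest), rep("gap", n_gap))
  habitat <- c(rep(c("mid", "late"), length.out = n_forest),
               rep("early", n_gap))
  base <- ifelse(ecotype == "gap", 0.7 + effect_size, 0.7)
  bats <- c("C_castanea", "C_sowelli", "C_perspicillata")
  out <- data.frame(
    piper_species = sprintf("Piper_%s%02d", ifelse(ecotype == "gap", "G", "F"),
                            c(seq_len(n_forest), seq_len(n_gap))),
    ecotype = ecotype, habitat = habitat)
  with_seed(seed, {
    sp_effect <- rnorm(n, 0, noise_sd / 2)
    for (b in bats) {
      v <- base + sp_effect + rnorm(n, 0, noise_sd)
      out[[b]] <- pmin(pmax(v, 0), 95)
    }
    out$max_pct <- do.call(pmax, out[bats])
    out$avg_pct <- rowMeans(out[bats])
    out
  })
}

#' Generate a synthetic fruit-VOC emission matrix
#'
#' Species-by-compound emission-per-weight matrix with log-normal abundances.
#' Fifteen "common" compounds (the first fifteen columns) are present in all
#' species at high abundance, emulating the ubiquitous scent-bouquet
#' components; the remaining compounds are sporadic (per-compound presence
#' probability drawn between 0.05 and 0.6) and low-abundance. The designated
#' affected compounds (a subset of the common ones) have their gap-species
#' log-mean shifted by `log_fold_change`.
#'
#' Defaults mirror the compiled chemical dataset: 21 species (13 forest, 8
#' gap) by 249 VOCs, with 6 ecotype-shifted compounds.
#'
#' @param n_forest,n_gap Number of forest and gap species.
#' @param n_compounds Total number of VOC columns (>= 15).
#' @param n_affected Number of ecotype-shifted compounds (<= 15).
#' @param log_fold_change Shift of the gap log-mean on the natural-log scale
#'   (default 3, i.e. about a twenty-fold emission difference: the designed
#'   chemotype contrast).
#' @param sdlog Log-scale standard deviation of abundances.
#' @param seed Integer seed.
#' @return A data frame with `species`, `ecotype` and one numeric column per
#'   compound (`VOC001`, ...). The designed compounds are recorded in
#'   `attr(, "affected_compounds")`.
#' @export
generate_voc_matrix <- function(n_forest = 13, n_gap = 8, n_compounds = 249,
                                n_affected = 6, log_fold_change = 3,
                                sdlog = 1, seed = NULL) {
  if (n_compounds < 15) stop_carollia("n_compounds must be >= 15")
  if (n_affected > 15) stop_carollia("n_affected must be <= 15")
  n <- n_forest + n_gap
  ecotype <- c(rep("forest", n_forest), rep("gap", n_gap))
  compounds <- sprintf("VOC%03d", seq_len(n_compounds))
  affected <- compounds[seq_len(n_affected)]
  out <- data.frame(species = sprintf("Piper_sp%02d", seq_len(n)),
                    ecotype = ecotype)
  with_seed(seed, {
    pres_p <- c(rep(1, 15), runif(n_compounds - 15, 0.05, 0.6))
    meanlog <- c(rep(4, 15), rep(0, n_compounds - 15))
    for (j in seq_len(n_compounds)) {
      mu <- rep(meanlog[j], n)
      if (compounds[j] %in% affected) {
        mu[ecotype == "gap"] <- mu[ecotype == "gap"] + log_fold_change
      }
      present <- runif(n) < pres_p[j]
      out[[compounds[j]]] <- ifelse(present, exp(rnorm(n, mu, sdlog)), 0)
    }
    structure(out, affected_compounds = affected)
  })
}

#' Generate a random ultrametric species phylogeny
#'
#' Coalescent (ultrametric) tree with the requested tip labels, used as the
#' stand-in for a time-calibrated species-level phylogeny when testing
#' phylogenetic-signal estimation.
#'
#' @param n_tips Number of tips (ignored when `tip_labels` is given).
#' @param tip_labels Optional tip names (e.g. VOC-matrix species).
#' @param seed Integer seed.
#' @return An [ape::rcoal()] `phylo` object.
#' @export
generate_tree <- function(n_tips = 32, tip_labels = NULL, seed = NULL) {
  if (!is.null(tip_labels)) n_tips <- length(tip_labels)
  if (n_tips < 3) stop_carollia("need at least 3 tips")
  with_seed(seed, {
    tr <- ape::rcoal(n_tips, tip.label = tip_labels %||%
                       paste0("t", seq_len(n_tips)))
    tr
  })
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Draws one trait realization with covariance `sigma^2 * vcv(tree)`,
#' used for calibrating Blomberg's K (expected value 1 under Brownian
#' motion).
#'
#' @param tree A `phylo` object.
#' @param sigma Brownian rate (standard deviation per unit branch length).
#' @param seed Integer seed.
#' @return Named numeric vector over the tips.
#' @export
sim_bm_trait <- function(tree, sigma = 1, seed = NULL) {
  C <- ape::vcv(tree)
  L <- chol(C)
  with_seed(seed, {
    x <- drop(crossprod(L, rnorm(nrow(C)))) * sigma
    setNames(x, rownames(C))
  })
}
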