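VISIT_BEHAVIORS <- c("flyby_visit", "inspect_fruit", "remove_fruit",
                     "eat_fruit", "whole_plant_consumption")
ECOTYPES <- c("forest", "gap")
HABITATS <- c("early", "mid", "late")

validate_events <- function(df, source = "events") {
  required <- c("plant_id", "piper_species", "ecotype", "habitat",
                "visitor_taxon", "behavior", "timestamp")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_carollia(source, ": missing column(s): ",
                  paste(missing, collapse = ", "))
  }
  bad <- which(!df$behavior %in% VISIT_BEHAVIORS)
  if (length(bad)) {
    stop_carollia(source, ": unknown behavior '", df$behavior[bad[1]],
                  "' in row ", bad[1])
  }
  bad <- which(!df$ecotype %in% ECOTYPES)
  if (length(bad)) {
    stop_carollia(source, ": unknown ecotype '", df$ecotype[bad[1]],
                  "' in row ", bad[1])
  }
  bad <- which(!df$habitat %in% HABITATS)
  if (length(bad)) {
    stop_carollia(source, ": unknown habitat '", df$habitat[bad[1]],
                  "' in row ", bad[1])
  }
  if (!inherits(df$timestamp, "POSIXct")) {
    s <- as.character(df$timestamp)
    ts <- as.POSIXct(strptime(s, "%Y-%m-%d %H:%M:%S", tz = ""))
    na <- is.na(ts)
    if (any(na)) {
      ts[na] <- as.POSIXct(strptime(s[na], "%Y-%m-%d %H:%M", tz = ""))
    }
    if (anyNA(ts)) {
      stop_carollia(source, ": malformed timestamp in row ",
                    which(is.na(ts))[1])
    }
    df$timestamp <- ts
  }
  df
}

#' Load a camera-trap visit-event log
#'
#' Reads and validates an annotation log: one row per observed visit with
#' the plant, *Piper* species, ecotype (forest/gap), succession habitat
#' (early/mid/late), visitor taxon (free label: bat, tanager, wasp, ...),
#' behavior (one of `flyby_visit`, `inspect_fruit`, `remove_fruit`,
#' `eat_fruit`, `whole_plant_consumption`) and a local timestamp. Unknown
#' behaviors or malformed timestamps are rejected with the offending row
#' number.
#'
#' @param path CSV file path.
#' @return A validated data frame of events with parsed `timestamp`.
#' @examples
#' ev <- load_events(system.file("extdata", "example_events.csv",
#'                               package = "carollia"))
#' tabulate_interactions(ev, group_by = "ecotype")
#' @export
load_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df$timestamp <- as.POSIXct(character())
    return(validate_events(df, source = path))
  }
  validate_events(df, source = path)
}

is_bat <- function(taxon) tolower(trimws(taxon)) == "bat"

#' Tabulate bat and non-bat interactions
#'
#' Aggregates a visit-event log into interaction counts per group: bat fruit
#' collections (bat events with `remove_fruit`), bat visitations (bat events
#' with `flyby_visit` or `inspect_fruit`, i.e. flying by or inspecting fruit
#' without removal), and all other (non-bat) visitations.
#'
#' @param events A validated event data frame ([load_events()] or
#'   [generate_event_log()]).
#' @param group_by `"species"`, `"ecotype"` or `"habitat"`.
#' @param modality Optional filter on an (optional) `modality` column
#'   (e.g. `"camera"`, `"acoustic"`), so merged-modality tables remain
#'   decomposable into camera-only and acoustic-only counts.
#' @return A data frame (one row per group) with columns
#'   `bat_fruit_collections`, `bat_visitations`, `other_visitations`.
#' @export
tabulate_interactions <- function(events,
                                  group_by = c("species", "ecotype",
                                               "habitat"),
                                  modality = NULL) {
  group_by <- match.arg(group_by)
  events <- validate_events(events)
  if (!is.null(modality)) {
    if (!"modality" %in% names(events)) {
      stop_carollia("events have no `modality` column to filter on")
    }
    events <- events[events$modality %in% modality, , drop = FALSE]
  }
  g <- switch(group_by, species = events$piper_species,
              ecotype = events$ecotype, habitat = events$habitat)
  bat <- is_bat(events$visitor_taxon)
  lv <- sort(unique(g))
  cnt <- function(sel) {
    t <- table(factor(g[sel], levels = lv))
    as.integer(t)
  }
  data.frame(group = lv,
             bat_fruit_collections = cnt(bat & events$behavior ==
                                           "remove_fruit"),
             bat_visitations = cnt(bat & events$behavior %in%
                                     c("flyby_visit", "inspect_fruit")),
             other_visitations = cnt(!bat))
}

#' Temporal activity profile
#'
#' Bins events by hour of day or by month. Hour bins are anchored at sunset:
#' the first bin is \[17:00, 18:00) local time, wrapping past midnight to
#' 16:59. `counts` mode sums events per bin; `species_binary` mode counts the
#' number of distinct *Piper* species with at least one event in the bin.
#'
#' @param events A validated event data frame.
#' @param axis `"hour"` or `"month"`.
#' @param mode `"counts"` or `"species_binary"`.
#' @param behaviors Optional subset of behaviors to include.
#' @return A data frame with `bin` (ordered labels) and `value`.
#' @export
activity_profile <- function(events, axis = c("hour", "month"),
                             mode = c("counts", "species_binary"),
                             behaviors = NULL) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  events <- validate_events(events)
  if (!is.null(behaviors)) {
    events <- events[events$behavior %in% behaviors, , drop = FALSE]
  }
  if (axis == "hour") {
    hrs <- as.integer(format(events$timestamp, "%H"))
    idx <- (hrs - 17L) %% 24L
    levels_idx <- 0:23
    labels <- sprintf("%02d:00", (17L + levels_idx) %% 24L)
  } else {
    idx <- as.integer(format(events$timestamp, "%m")) - 1L
    levels_idx <- 0:11
    labels <- month.abb
  }
  f <- factor(idx, levels = levels_idx)
  value <- if (mode == "counts") {
    as.integer(table(f))
  } else {
    vapply(levels_idx, function(b)
      length(unique(events$piper_species[idx == b])), integer(1))
  }
  data.frame(bin = labels, value = value)
}
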