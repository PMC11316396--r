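write_event_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

toy_events <- function() {
  data.frame(
    plant_id = c("p1", "p2", "p3"),
    piper_species = c("P. reticulatum", "P. generalense", "P. reticulatum"),
    ecotype = c("gap", "forest", "gap"),
    habitat = c("mid", "mid", "mid"),
    visitor_taxon = c("bat", "bat", "tanager"),
    behavior = c("remove_fruit", "inspect_fruit", "eat_fruit"),
    timestamp = c("2019-06-01 18:30:00", "2019-06-01 21:00:00",
                  "2019-06-02 09:15:00"))
}

test_that("event logs load, validate, and reject bad rows by number", {
  f <- write_event_csv(toy_events())
  ev <- load_events(f)
  expect_equal(nrow(ev), 3L)
  expect_s3_class(ev$timestamp, "POSIXct")
  expect_equal(format(ev$timestamp[1], "%H:%M"), "18:30")

  empty <- toy_events()[0, ]
  expect_equal(nrow(load_events(write_event_csv(empty))), 0L)

  bad <- toy_events()
  bad$behavior[2] <- "levitating"
  expect_error(load_events(write_event_csv(bad)), "levitating.*row 2")

  badts <- toy_events()
  badts$timestamp[3] <- "not-a-time"
  expect_error(load_events(write_event_csv(badts)), "timestamp in row 3")
})

test_that("interaction tabulation matches the defining rules", {
  ev <- toy_events()
  tab <- tabulate_interactions(ev, group_by = "ecotype")
  gap <- tab[tab$group == "gap", ]
  forest <- tab[tab$group == "forest", ]
  expect_equal(gap$bat_fruit_collections, 1L)
  expect_equal(gap$other_visitations, 1L)
  expect_equal(forest$bat_visitations, 1L)
  expect_equal(forest$bat_fruit_collections, 0L)
})

test_that("tabulation equals a brute-force recount and is order-invariant", {
  ev <- generate_event_log(n_nights = 120, seed = 11)
  tab <- tabulate_interactions(ev, group_by = "species")
  oracle <- oracle_tally(ev, "piper_species")
  for (i in seq_len(nrow(tab))) {
    o <- oracle[[tab$group[i]]]
    expect_equal(tab$bat_fruit_collections[i], unname(o["bat_fruit_collections"]))
    expect_equal(tab$bat_visitations[i], unname(o["bat_visitations"]))
    expect_equal(tab$other_visitations[i], unname(o["other_visitations"]))
  }
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(tabulate_interactions(shuffled, group_by = "species"), tab)

  # conservation: group totals sum to the overall tally
  tab_h <- tabulate_interactions(ev, group_by = "habitat")
  expect_equal(sum(tab_h$bat_fruit_collections + tab_h$bat_visitations +
                     tab_h$other_visitations),
               sum(tab$bat_fruit_collections + tab$bat_visitations +
                     tab$other_visitations))
})

test_that("modality-tagged counts remain decomposable", {
  ev <- toy_events()
  ev$modality <- c("camera", "acoustic", "camera")
  merged <- tabulate_interactions(ev, group_by = "ecotype")
  cam <- tabulate_interactions(ev, group_by = "ecotype",
                               modality = "camera")
  aco <- tabulate_interactions(ev, group_by = "ecotype",
                               modality = "acoustic")
  expect_equal(sum(cam$bat_visitations) + sum(aco$bat_visitations),
               sum(merged$bat_visitations))
  expect_error(tabulate_interactions(toy_events(), modality = "camera"),
               "modality")
})

test_that("activity profiles are sunset-anchored and conserve counts", {
  ev <- toy_events()
  prof <- activity_profile(ev, axis = "hour", mode = "counts")
  expect_equal(prof$bin[1], "17:00")
  expect_equal(prof$value[prof$bin == "18:00"], 1L)

  # five same-species events in one hour collapse to one in binary mode
  ev5 <- ev[rep(1, 5), ]
  prof5 <- activity_profile(ev5, axis = "hour", mode = "species_binary")
  expect_equal(prof5$value[prof5$bin == "18:00"], 1L)
  expect_equal(sum(prof5$value), 1L)

  big <- generate_event_log(n_nights = 90, seed = 12)
  prof_b <- activity_profile(big, axis = "hour", mode = "counts")
  expect_equal(sum(prof_b$value), nrow(big))
  # independent recount of one bin
  h20 <- sum(format(big$timestamp, "%H") == "20")
  expect_equal(prof_b$value[prof_b$bin == "20:00"], h20)
  # binary mode never exceeds the number of species seen
  prof_s <- activity_profile(big, axis = "month", mode = "species_binary")
  expect_lte(max(prof_s$value), length(unique(big$piper_species)))
})
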