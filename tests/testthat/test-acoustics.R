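test_that("band-pass preserves in-band tones and rejects out-of-band ones", {
  tone70 <- make_test_clip(70)
  out <- bandpass(tone70, 30, 110)
  gain_db <- 20 * log10(sd(out$samples) / sd(tone70$samples))
  expect_lt(abs(gain_db), 1)

  tone10 <- make_test_clip(10)
  out10 <- bandpass(tone10, 30, 110, order = 4)
  att_db <- 20 * log10(sd(out10$samples) / sd(tone10$samples))
  expect_lt(att_db, -40)   # two-pass order-4 Butterworth, >=40 dB down

  zeros <- audio_clip(rep(0, 5000), 256000)
  expect_equal(bandpass(zeros, 30, 110)$samples, rep(0, 5000))

  expect_error(bandpass(tone70, 30, 130), "Nyquist")
  expect_error(bandpass(tone70, 110, 30), "low_khz < high_khz")
})

test_that("peak_frequency finds the dominant spectral component", {
  expect_equal(peak_frequency(make_test_clip(65)), 65, tolerance = 0.26)
  # 30 kHz at amplitude 1 + 70 kHz at amplitude 2 -> 70 kHz wins
  expect_equal(peak_frequency(make_test_clip(c(30, 70), c(1, 2))), 70,
               tolerance = 0.26)
  # short clip falls back to a single periodogram, with a message
  short <- audio_clip(sin(2 * pi * 0.1 * (1:512)), 256000)
  expect_message(welch_psd(short), "single periodogram")
})

test_that("peak_frequency equals an independent averaged-periodogram oracle", {
  for (i in 1:10) {
    sc <- scene_spec(clip_duration_s = 0.3,
                     noise_model = sample(c("white", "pink",
                                            "low_frequency_clutter"), 1),
                     seed = 100 + i,
                     calls = if (i %% 2 == 0) list(
                       call_spec("FM_HARMONIC_CAROLLIA", 40, 25, 2, 2,
                                 onset_s = 0.1)) else list())
    clip <- generate_clip(sc)$clip
    expect_equal(peak_frequency(clip),
                 oracle_peak_frequency(clip$samples, clip$sample_rate_hz))
  }
})

test_that("screen_clip applies the band and window decision", {
  pos <- generate_clip(carollia_scene(n_calls = 6, snr_db = 20, seed = 21,
                                      clip_duration_s = 2))$clip
  r <- screen_clip(pos, run_specific())
  expect_true(r$bat_positive)
  expect_equal(r$run_label, "specific")

  neg <- generate_clip(clutter_scene(seed = 22, clip_duration_s = 2))$clip
  expect_false(screen_clip(neg, run_specific())$bat_positive)

  tone90 <- make_test_clip(90)
  expect_false(screen_clip(tone90, run_specific())$bat_positive)
})

test_that("run parameter invariants hold", {
  expect_error(run_parameters("x", 110, 30, c(60, 80)), "below")
  expect_error(run_parameters("x", 30, 110, c(20, 80)), "within")
  expect_silent(run_parameters("x", 30, 110, c(60, 80)))
})

test_that("two-pass screening unions the runs into one tagged queue", {
  pos <- generate_clip(carollia_scene(n_calls = 6, snr_db = 20, seed = 31,
                                      clip_duration_s = 2),
                       clip_id = "pos")$clip
  neg <- generate_clip(clutter_scene(seed = 32, clip_duration_s = 2),
                       clip_id = "neg")$clip
  out <- two_pass_screen(list(pos, neg))
  expect_equal(nrow(out$results), 4L)
  q <- out$review_queue
  expect_equal(sum(q$clip_id == "pos"), 1L)  # flagged once, not per run
  expect_true(q$specific[q$clip_id == "pos"] && q$sensitive[q$clip_id == "pos"])
  expect_false("neg" %in% q$clip_id)

  empty <- two_pass_screen(list())
  expect_equal(nrow(empty$review_queue), 0L)
  expect_error(two_pass_screen(list(pos), run_specific(), run_specific()),
               "distinct")
})

test_that("sensitive run recall is at least the specific run recall", {
  # scaled-down version of the screening-soundness check (the full-size
  # version runs in the acceptance suite)
  n <- 8
  hits <- matrix(FALSE, n, 2, dimnames = list(NULL, c("specific", "sensitive")))
  for (i in seq_len(n)) {
    clip <- generate_clip(carollia_scene(n_calls = 5, snr_db = c(15, 25),
                                         seed = 600 + i,
                                         clip_duration_s = 2))$clip
    hits[i, 1] <- screen_clip(clip, run_specific())$bat_positive
    hits[i, 2] <- screen_clip(clip, run_sensitive())$bat_positive
  }
  expect_gte(mean(hits[, "sensitive"]), mean(hits[, "specific"]))
})
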