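test_that("spectrogram geometry, rounding, and energy bookkeeping", {
  tone <- make_test_clip(64, dur_s = 0.05)
  spg <- clip_spectrogram(tone)
  expect_equal(nrow(spg$power), 512 / 2 + 1)
  # hop 512 * 0.05 = 25.6 is floored to 25 samples
  expect_equal(spg$hop, 25L)
  # dominant row at the 64 kHz bin
  expect_equal(spg$freq_khz[which.max(rowSums(spg$power))], 64,
               tolerance = 0.26)
  # Parseval: total one-sided power / nfft equals summed windowed energy
  x <- tone$samples
  w <- spg$window
  starts <- seq(1L, length(x) - 512L + 1L, by = spg$hop)
  direct <- sum(vapply(starts, function(s)
    sum((x[s:(s + 511L)] * w)^2), numeric(1)))
  expect_equal(sum(spg$power) / 512, direct, tolerance = 0.01 * direct)

  expect_error(clip_spectrogram(audio_clip(rnorm(100), 256000)), "shorter")
})

test_that("noise-only clips yield no call intervals almost always", {
  n_fp <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    clip <- generate_clip(clutter_scene(seed = 700 + i,
                                        clip_duration_s = 0.3))$clip
    iv <- segment_calls(clip_spectrogram(clip))
    if (nrow(iv) > 0) n_fp <- n_fp + 1
  }
  expect_lte(n_fp / n_rep, 0.05)
})

test_that("segmentation recovers true call intervals in order", {
  sc <- scene_spec(clip_duration_s = 0.3, noise_level = 0.05, seed = 41,
                   calls = list(
                     call_spec("FM_HARMONIC_CAROLLIA", 40, 25, 2, 2,
                               duration_ms = 2, amplitude_db_re_noise = 20,
                               onset_s = 0.10),
                     call_spec("FM_HARMONIC_CAROLLIA", 40, 25, 2, 2,
                               duration_ms = 2, amplitude_db_re_noise = 20,
                               onset_s = 0.20)))
  out <- generate_clip(sc)
  iv <- segment_calls(clip_spectrogram(out$clip))
  expect_equal(nrow(iv), 2L)
  expect_true(all(diff(iv$start_s) > 0))
  for (k in 1:2) {
    expect_lt(iv$start_s[k], out$truth$calls$offset_s[k])
    expect_gt(iv$end_s[k], out$truth$calls$onset_s[k])
  }

  # single call: exactly one interval
  sc1 <- scene_spec(clip_duration_s = 0.3, noise_level = 0.05, seed = 42,
                    calls = list(call_spec("FM_HARMONIC_CAROLLIA", 40, 25,
                                           2, 2, duration_ms = 2,
                                           amplitude_db_re_noise = 20,
                                           onset_s = 0.15)))
  iv1 <- segment_calls(clip_spectrogram(generate_clip(sc1)$clip))
  expect_equal(nrow(iv1), 1L)
})

test_that("measurement recovers the main-harmonic sweep parameters", {
  # single-track linear sweep 80 -> 50 kHz over 2 ms; with the Hann call
  # envelope the -20 dB spectral support pulls in ~3 kHz from each edge
  sc <- scene_spec(clip_duration_s = 0.2, noise_level = 0.05, seed = 51,
                   calls = list(call_spec("FM_NO_HARMONIC", 80, 50, 1, 1,
                                          duration_ms = 2,
                                          amplitude_db_re_noise = 25,
                                          onset_s = 0.1)))
  spg <- clip_spectrogram(generate_clip(sc)$clip)
  iv <- segment_calls(spg)
  expect_equal(nrow(iv), 1L)
  m <- measure_call(spg, iv[1, ])
  expect_equal(m$fmin_khz, 50, tolerance = 5)
  expect_equal(m$fmax_khz, 80, tolerance = 5)
  expect_equal(m$delta_f_khz, 30, tolerance = 8)
  expect_equal(m$duration_ms, 2, tolerance = 2)
  expect_equal(m$n_harmonics, 1L)
})

test_that("constant-frequency calls measure as near-zero bandwidth", {
  sc <- scene_spec(clip_duration_s = 0.2, noise_level = 0.05, seed = 52,
                   calls = list(call_spec("FM_CF", 70, 70, 1, 1,
                                          duration_ms = 8,
                                          amplitude_db_re_noise = 25,
                                          onset_s = 0.1)))
  spg <- clip_spectrogram(generate_clip(sc)$clip)
  iv <- segment_calls(spg)
  m <- measure_call(spg, iv[1, ])
  bin_khz <- spg$freq_khz[2] - spg$freq_khz[1]
  expect_lte(m$bw90_khz, 2 * bin_khz)
  expect_equal(m$fpeak_khz, 70, tolerance = bin_khz)
})

test_that("measurement invariants hold across generated calls", {
  seeds <- 60:67
  for (s in seeds) {
    sc <- carollia_scene(n_calls = 2, snr_db = c(15, 25), seed = s,
                         clip_duration_s = 0.5)
    spg <- clip_spectrogram(generate_clip(sc)$clip)
    iv <- segment_calls(spg)
    for (i in seq_len(nrow(iv))) {
      m <- measure_call(spg, iv[i, ])
      expect_lte(m$duration90_ms, m$duration_ms)
      expect_lte(m$fmin_khz, m$fpeak_khz)
      expect_lte(m$fpeak_khz, m$fmax_khz)
      expect_equal(m$delta_f_khz, m$fmax_khz - m$fmin_khz)
      expect_lte(m$bw90_khz, m$delta_f_khz + 1e-9)
      expect_true(is.finite(m$snr_db))
      expect_lte(m$main_harmonic_index, max(m$n_harmonics, m$main_harmonic_index))
    }
  }
})

test_that("degenerate single-frame intervals are flagged, not dropped", {
  sc <- scene_spec(clip_duration_s = 0.1, noise_level = 0.05, seed = 53,
                   calls = list(call_spec("FM_NO_HARMONIC", 70, 60, 1, 1,
                                          duration_ms = 2,
                                          amplitude_db_re_noise = 25,
                                          onset_s = 0.05)))
  spg <- clip_spectrogram(generate_clip(sc)$clip)
  j <- which.min(abs(spg$time_s - 0.051))
  m <- measure_call(spg, list(start_frame = j, end_frame = j))
  expect_true(m$degenerate)
  expect_equal(m$duration_ms, spg$hop / spg$sample_rate_hz * 1000)
  expect_error(measure_call(spg, list(start_frame = 0, end_frame = 5)),
               "within")
})

test_that("classification follows the call-type decision tree", {
  classify_from <- function(calls, seed, band = c(40, 110)) {
    spg <- clip_spectrogram(generate_clip(
      scene_spec(clip_duration_s = 0.3, noise_level = 0.05, seed = seed,
                 calls = calls))$clip)
    iv <- segment_calls(spg, band_khz = band)
    lapply(seq_len(nrow(iv)), function(i) measure_call(spg, iv[i, ]))
  }
  # 2-harmonic downward FM, main peak ~65-70 kHz, high SNR -> Carollia
  ms <- classify_from(list(call_spec("FM_HARMONIC_CAROLLIA", 40, 25, 2, 2,
                                     duration_ms = 2.5,
                                     amplitude_db_re_noise = 20,
                                     onset_s = 0.15)), 71)
  expect_equal(classify_call(ms[[1]]), "FM_HARMONIC_CAROLLIA")
  # single-track FM sweep -> no harmonics
  ms <- classify_from(list(call_spec("FM_NO_HARMONIC", 80, 50, 1, 1,
                                     duration_ms = 2,
                                     amplitude_db_re_noise = 20,
                                     onset_s = 0.15)), 72)
  expect_equal(classify_call(ms[[1]]), "FM_NO_HARMONIC")
  # sweep-constant-sweep -> FM-CF-FM
  ms <- classify_from(list(call_spec("FM_CF_FM", 65, 50, 1, 1,
                                     duration_ms = 10,
                                     amplitude_db_re_noise = 25,
                                     onset_s = 0.15)), 73)
  expect_equal(classify_call(ms[[1]]), "FM_CF_FM")
  # low-frequency call (fmax < 40) is measurable under a widened band but
  # discarded by the classifier
  ms <- classify_from(list(call_spec("FM_NO_HARMONIC", 36, 28, 1, 1,
                                     duration_ms = 3,
                                     amplitude_db_re_noise = 25,
                                     onset_s = 0.15)), 74,
                      band = c(25, 110))
  expect_true(is.na(classify_call(ms[[1]])))
  # dense train -> feeding buzz regardless of shape
  expect_equal(classify_call(ms[[1]], ici_ms = 4), "FEEDING_BUZZ")
})

test_that("Carollia labels always require >= 2 harmonics and the window", {
  for (s in 80:85) {
    sc <- carollia_scene(n_calls = 2, seed = s, clip_duration_s = 0.5)
    spg <- clip_spectrogram(generate_clip(sc)$clip)
    iv <- segment_calls(spg)
    for (i in seq_len(nrow(iv))) {
      m <- measure_call(spg, iv[i, ])
      lab <- classify_call(m)
      if (!is.na(lab) && lab == "FM_HARMONIC_CAROLLIA") {
        expect_gte(m$n_harmonics, 2L)
        expect_gte(m$fpeak_khz, 60)
        expect_lte(m$fpeak_khz, 80)
        expect_gte(m$snr_db, 10)
      }
      if (!is.na(lab)) expect_gte(m$fmax_khz, 40)
    }
  }
})
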