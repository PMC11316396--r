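CALL_TYPES <- c("FM_HARMONIC_CAROLLIA", "FM_NO_HARMONIC", "FM_CF_FM",
                "FM_CF", "FM_QCF", "FEEDING_BUZZ")

#' Specify one synthetic echolocation call
#'
#' Describes a frequency-modulated (FM) call as a fundamental sweep plus
#' phase-locked harmonics; harmonic `k` sweeps `k` times the fundamental.
#' Sweeps are linear in frequency. Call shapes:
#'
#' * `FM_HARMONIC_CAROLLIA`, `FM_NO_HARMONIC`, `FEEDING_BUZZ`: a single
#'   downward linear sweep from `fundamental_start_khz` to
#'   `fundamental_end_khz`.
#' * `FM_CF_FM`: sweep down to the midpoint frequency (20% of the duration),
#'   hold it (60%), then sweep down to the end frequency (20%).
#' * `FM_CF`: sweep down to the end frequency (30%), then hold it (70%).
#' * `FM_QCF`: steep sweep to a knee at 15% of the frequency span above the
#'   end frequency (30% of the duration), then a shallow quasi-constant sweep
#'   to the end frequency (70%).
#'
#' @param call_type One of `"FM_HARMONIC_CAROLLIA"`, `"FM_NO_HARMONIC"`,
#'   `"FM_CF_FM"`, `"FM_CF"`, `"FM_QCF"`, `"FEEDING_BUZZ"`.
#' @param fundamental_start_khz,fundamental_end_khz Fundamental frequency at
#'   call onset and offset, kHz. Downward sweeps require start >= end.
#' @param n_harmonics Number of harmonics synthesized (>= 1).
#' @param main_harmonic_index 1-based index of the loudest harmonic (the
#'   second for *Carollia*).
#' @param duration_ms Call duration in ms (> 0).
#' @param amplitude_db_re_noise Peak amplitude of the main harmonic relative
#'   to the scene noise RMS, in dB (the call's SNR).
#' @param onset_s Call onset within the clip, seconds.
#' @param harmonic_rel_db Amplitude of non-main harmonics relative to the
#'   main harmonic, dB (default -6).
#' @return An object of class `call_spec`.
#' @examples
#' call_spec("FM_HARMONIC_CAROLLIA", 40, 25, n_harmonics = 2,
#'           main_harmonic_index = 2, duration_ms = 2.5,
#'           amplitude_db_re_noise = 20, onset_s = 1)
#' @export
call_spec <- function(call_type, fundamental_start_khz, fundamental_end_khz,
                      n_harmonics = 1L, main_harmonic_index = 1L,
                      duration_ms = 2.5, amplitude_db_re_noise = 20,
                      onset_s = 0, harmonic_rel_db = -6) {
  call_type <- match.arg(call_type, CALL_TYPES)
  assert_scalar_number(fundamental_start_khz, "fundamental_start_khz", lower = 0)
  assert_scalar_number(fundamental_end_khz, "fundamental_end_khz", lower = 0)
  assert_scalar_number(duration_ms, "duration_ms")
  if (duration_ms <= 0) stop_carollia("duration_ms must be > 0")
  if (fundamental_start_khz < fundamental_end_khz) {
    stop_carollia("downward FM sweep requires fundamental_start_khz >= ",
                  "fundamental_end_khz")
  }
  n_harmonics <- as.integer(n_harmonics)
  main_harmonic_index <- as.integer(main_harmonic_index)
  if (n_harmonics < 1L) stop_carollia("n_harmonics must be >= 1")
  if (main_harmonic_index < 1L || main_harmonic_index > n_harmonics) {
    stop_carollia("main_harmonic_index must lie in 1..n_harmonics")
  }
  assert_scalar_number(onset_s, "onset_s", lower = 0)
  structure(list(call_type = call_type,
                 fundamental_start_khz = fundamental_start_khz,
                 fundamental_end_khz = fundamental_end_khz,
                 n_harmonics = n_harmonics,
                 main_harmonic_index = main_harmonic_index,
                 duration_ms = duration_ms,
                 amplitude_db_re_noise = amplitude_db_re_noise,
                 onset_s = onset_s,
                 harmonic_rel_db = harmonic_rel_db),
            class = "call_spec")
}

# Fundamental instantaneous frequency (kHz) at normalized times u in [0, 1].
fundamental_trajectory <- function(spec, u) {
  f0 <- spec$fundamental_start_khz
  f1 <- spec$fundamental_end_khz
  switch(spec$call_type,
    FM_CF_FM = {
      fc <- (f0 + f1) / 2
      ifelse(u < 0.2, f0 + (fc - f0) * u / 0.2,
             ifelse(u < 0.8, fc, fc + (f1 - fc) * (u - 0.8) / 0.2))
    },
    FM_CF = ifelse(u < 0.3, f0 + (f1 - f0) * u / 0.3, f1),
    FM_QCF = {
      knee <- f1 + 0.15 * (f0 - f1)
      ifelse(u < 0.3, f0 + (knee - f0) * u / 0.3,
             knee + (f1 - knee) * (u - 0.3) / 0.7)
    },
    # plain linear downward sweep for the FM family
    f0 + (f1 - f0) * u
  )
}

#' Specify a synthetic ultrasonic scene
#'
#' One duty-cycled logger clip: a noise background plus zero or more
#' echolocation calls. Defaults mirror field deployments of full-spectrum
#' loggers: 10-s clips sampled at 256 kHz.
#'
#' Noise models:
#' * `"white"`: flat-spectrum Gaussian noise.
#' * `"pink"`: 1/f-spectrum noise (ambient outdoor noise decays with
#'   frequency).
#' * `"low_frequency_clutter"`: pink noise low-passed at 20 kHz (wind and
#'   vegetation clutter) plus a pink broadband floor 20 dB down, the
#'   background regime typical of tropical-forest recordings.
#'
#' @param clip_duration_s Clip length, seconds (default 10).
#' @param sample_rate_hz Sampling rate, Hz (default 256000).
#' @param noise_model `"white"`, `"pink"` or `"low_frequency_clutter"`.
#' @param noise_level Noise RMS amplitude on the nominal waveform scale.
#' @param calls List of [call_spec()] objects.
#' @param seed Integer seed making the rendered clip reproducible.
#' @param start_time Clip start timestamp (`POSIXct`), used for
#'   AudioMoth-style file naming; optional.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(clip_duration_s = 10, sample_rate_hz = 256000,
                       noise_model = c("low_frequency_clutter", "white", "pink"),
                       noise_level = 0.05, calls = list(), seed = NULL,
                       start_time = NULL) {
  noise_model <- match.arg(noise_model)
  assert_scalar_number(clip_duration_s, "clip_duration_s", lower = 1e-3)
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1)
  assert_scalar_number(noise_level, "noise_level", lower = 0)
  if (!is.list(calls) || !all(vapply(calls, inherits, TRUE, "call_spec"))) {
    stop_carollia("`calls` must be a list of call_spec objects")
  }
  nyq_khz <- sample_rate_hz / 2000
  for (cs in calls) {
    if (cs$onset_s + cs$duration_ms / 1000 > clip_duration_s) {
      stop_carollia("call at onset ", cs$onset_s,
                    " s does not fit within the clip")
    }
    fmax <- cs$n_harmonics * max(cs$fundamental_start_khz,
                                 cs$fundamental_end_khz)
    if (fmax >= nyq_khz) {
      stop_carollia("call harmonic reaches ", fmax,
                    " kHz, at or above the Nyquist frequency (", nyq_khz,
                    " kHz)")
    }
  }
  structure(list(clip_duration_s = clip_duration_s,
                 sample_rate_hz = sample_rate_hz,
                 noise_model = noise_model, noise_level = noise_level,
                 calls = calls, seed = seed, start_time = start_time),
            class = "scene_spec")
}

# Pink (1/f) noise via the Kellet 3-pole IIR approximation, unit RMS.
pink_noise <- function(n) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  x <- .iir_filter(b, a, rnorm(n))
  x / sd(x)
}

scene_noise <- function(model, n, fs, level) {
  if (level == 0) return(numeric(n))
  x <- switch(model,
    white = rnorm(n),
    pink = pink_noise(n),
    low_frequency_clutter = {
      lp <- signal::butter(4, 20000 / (fs / 2), type = "low")
      clutter <- zero_phase_filter(lp$b, lp$a, pink_noise(n))
      clutter <- clutter / sd(clutter)
      floor_bb <- pink_noise(n)
      y <- clutter + 0.1 * floor_bb       # broadband floor 20 dB down
      y / sd(y)
    })
  level * x
}

# Render one call as a sum of harmonic sweeps with a Hann envelope.
render_call <- function(spec, fs, ref_rms) {
  n <- max(2L, round(spec$duration_ms / 1000 * fs))
  u <- (seq_len(n) - 1) / (n - 1)
  f_khz <- fundamental_trajectory(spec, u)
  phase <- 2 * pi * cumsum(f_khz * 1000) / fs
  env <- 0.5 * (1 - cos(2 * pi * u))
  a_main <- ref_rms * 10^(spec$amplitude_db_re_noise / 20)
  rel <- 10^(spec$harmonic_rel_db / 20)
  y <- numeric(n)
  for (k in seq_len(spec$n_harmonics)) {
    amp <- if (k == spec$main_harmonic_index) a_main else a_main * rel
    y <- y + amp * sin(k * phase)
  }
  y * env
}

#' Render a synthetic ultrasonic clip with ground truth
#'
#' Synthesizes the scene waveform (noise background plus calls) and returns it
#' as an [audio_clip()] together with the per-call ground truth. Identical
#' seeds give bit-identical samples.
#'
#' @param spec A [scene_spec()].
#' @param clip_id Optional clip identifier carried into results.
#' @param ... Label metadata passed to [audio_clip()] (`plant_id`, `species`,
#'   `ecotype`, `habitat`).
#' @return A list with elements `clip` (an `audio_clip`) and `truth` (a list
#'   with `bat_present`, `carollia_present` and a per-call data frame `calls`
#'   holding true onsets/offsets and main-harmonic frequency parameters).
#' @examples
#' sc <- scene_spec(clip_duration_s = 0.5, calls = list(
#'   call_spec("FM_HARMONIC_CAROLLIA", 40, 25, 2, 2, onset_s = 0.2)), seed = 1)
#' out <- generate_clip(sc)
#' out$truth$bat_present
#' @export
generate_clip <- function(spec, clip_id = "clip", ...) {
  stopifnot(inherits(spec, "scene_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$clip_duration_s * fs)
  samples <- with_seed(spec$seed, {
    y <- scene_noise(spec$noise_model, n, fs, spec$noise_level)
    ref <- if (spec$noise_level > 0) spec$noise_level else 1
    for (cs in spec$calls) {
      w <- render_call(cs, fs, ref)
      i0 <- round(cs$onset_s * fs) + 1L
      idx <- i0:(i0 + length(w) - 1L)
      y[idx] <- y[idx] + w
    }
    y
  })
  truth_calls <- do.call(rbind, lapply(spec$calls, function(cs) {
    k <- cs$main_harmonic_index
    f0 <- k * cs$fundamental_start_khz
    f1 <- k * cs$fundamental_end_khz
    data.frame(call_type = cs$call_type,
               onset_s = cs$onset_s,
               offset_s = cs$onset_s + cs$duration_ms / 1000,
               duration_ms = cs$duration_ms,
               n_harmonics = cs$n_harmonics,
               main_harmonic_index = k,
               main_fmax_khz = max(f0, f1),
               main_fmin_khz = min(f0, f1),
               # Hann envelope peaks mid-call, so the spectral peak sits at
               # the mid-call instantaneous frequency of the main harmonic
               peak_khz = fundamental_trajectory(cs, 0.5) * k,
               snr_db = cs$amplitude_db_re_noise)
  }))
  truth <- list(
    bat_present = length(spec$calls) > 0L,
    carollia_present = any(vapply(spec$calls, function(cs)
      cs$call_type == "FM_HARMONIC_CAROLLIA", TRUE)),
    calls = truth_calls)
  clip <- audio_clip(samples, fs, start_time = spec$start_time,
                     clip_id = clip_id, ...)
  list(clip = clip, truth = truth)
}

#' Convenience scenes: a Carollia pass and a clutter-only clip
#'
#' `carollia_scene()` places a short train of *Carollia*-type calls (two to
#' three harmonics, fundamental sweeping roughly 40 to 25 kHz so the dominant
#' second harmonic peaks in the 60-80 kHz band) at random onsets in a
#' clutter-background clip. `clutter_scene()` is the matching noise-only
#' control.
#'
#' @param n_calls Number of calls in the pass (default 12, a bat commuting
#'   past the plant for about a second of the 10-s clip).
#' @param snr_db Single SNR or range to sample per call, dB.
#' @param seed Integer seed.
#' @param clip_duration_s,sample_rate_hz,noise_level Passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
carollia_scene <- function(n_calls = 12, snr_db = c(15, 25), seed = NULL,
                           clip_duration_s = 10, sample_rate_hz = 256000,
                           noise_level = 0.05) {
  pars <- with_seed(seed, {
    dur <- runif(n_calls, 2, 3)
    onset <- sort(runif(n_calls, 0.05, clip_duration_s - 0.05))
    list(dur = dur, onset = onset,
         f0 = runif(n_calls, 38, 42), f1 = runif(n_calls, 24, 28),
         nh = sample(2:3, n_calls, replace = TRUE),
         snr = if (length(snr_db) == 2L)
           runif(n_calls, snr_db[1], snr_db[2]) else rep(snr_db, n_calls))
  })
  calls <- lapply(seq_len(n_calls), function(i) {
    call_spec("FM_HARMONIC_CAROLLIA", pars$f0[i], pars$f1[i],
              n_harmonics = pars$nh[i], main_harmonic_index = 2L,
              duration_ms = pars$dur[i], amplitude_db_re_noise = pars$snr[i],
              onset_s = pars$onset[i])
  })
  scene_spec(clip_duration_s = clip_duration_s,
             sample_rate_hz = sample_rate_hz,
             noise_model = "low_frequency_clutter",
             noise_level = noise_level, calls = calls,
             seed = if (is.null(seed)) NULL else seed + 1)
}

#' @rdname carollia_scene
#' @export
clutter_scene <- function(seed = NULL, clip_duration_s = 10,
                          sample_rate_hz = 256000, noise_level = 0.05) {
  scene_spec(clip_duration_s = clip_duration_s,
             sample_rate_hz = sample_rate_hz,
             noise_model = "low_frequency_clutter",
             noise_level = noise_level, calls = list(), seed = seed)
}
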