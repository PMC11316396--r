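#' Ultrasonic audio clip container
#'
#' Bundles a waveform with its sampling rate and the field metadata used by
#' downstream tabulations (which plant, species, ecotype and habitat the
#' logger was deployed at).
#'
#' @param samples Numeric amplitude series (finite values).
#' @param sample_rate_hz Sampling rate, Hz (> 0).
#' @param start_time Optional `POSIXct` recording start time.
#' @param plant_id,species,ecotype,habitat Optional labels.
#' @param clip_id Clip identifier.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate_hz, start_time = NULL,
                       plant_id = NA_character_, species = NA_character_,
                       ecotype = NA_character_, habitat = NA_character_,
                       clip_id = "clip") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_carollia("`samples` must be a non-empty numeric vector")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_carollia("`samples` must be finite")
  }
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 start_time = start_time, plant_id = plant_id,
                 species = species, ecotype = ecotype, habitat = habitat,
                 clip_id = clip_id),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip %s: %.3f s at %g kHz>\n", x$clip_id,
              length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz / 1000))
  invisible(x)
}

#' Screening-run parameters
#'
#' One parameterization of the semi-automated screening pass: the Butterworth
#' band-pass edges and the peak-frequency decision window. The screening
#' algorithm is run twice, once with specific settings (band 30-110 kHz,
#' guarding against type I error) and once with sensitive settings (band
#' 20-100 kHz, guarding against type II error). Only the band edges of the
#' original runs are on record; the default decision windows bracket the
#' 60-80 kHz range of *Carollia* search-phase peak frequencies ([60, 80] for
#' the specific run, [55, 85] for the sensitive run) and are configurable.
#'
#' @param label Run label, `"specific"` or `"sensitive"` (free text allowed).
#' @param highpass_khz,lowpass_khz Band-pass edges, kHz (`highpass < lowpass`).
#' @param peak_window_khz Length-2 decision window, kHz, contained in the
#'   band.
#' @return An object of class `run_parameters`.
#' @export
run_parameters <- function(label, highpass_khz, lowpass_khz, peak_window_khz) {
  assert_scalar_number(highpass_khz, "highpass_khz", lower = 0)
  assert_scalar_number(lowpass_khz, "lowpass_khz", lower = 0)
  if (highpass_khz >= lowpass_khz) {
    stop_carollia("highpass_khz must be below lowpass_khz")
  }
  if (length(peak_window_khz) != 2L || peak_window_khz[1] >= peak_window_khz[2]) {
    stop_carollia("peak_window_khz must be an increasing length-2 vector")
  }
  if (peak_window_khz[1] < highpass_khz || peak_window_khz[2] > lowpass_khz) {
    stop_carollia("peak_window_khz must lie within the band-pass")
  }
  structure(list(label = label, highpass_khz = highpass_khz,
                 lowpass_khz = lowpass_khz,
                 peak_window_khz = as.numeric(peak_window_khz)),
            class = "run_parameters")
}

#' @rdname run_parameters
#' @export
run_specific <- function() {
  run_parameters("specific", 30, 110, c(60, 80))
}

#' @rdname run_parameters
#' @export
run_sensitive <- function() {
  run_parameters("sensitive", 20, 100, c(55, 85))
}

# Zero-phase IIR filtering: forward-backward application with odd-symmetric
# edge extension to suppress startup transients.
zero_phase_filter <- function(b, a, x) {
  npad <- min(3L * max(length(a), length(b)), length(x) - 1L)
  if (npad > 0L) {
    pre <- 2 * x[1] - x[(npad + 1):2]
    post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
    xx <- c(pre, x, post)
  } else {
    xx <- x
  }
  y <- .iir_filter(b, a, xx)
  y <- rev(.iir_filter(b, a, rev(y)))
  if (npad > 0L) y <- y[(npad + 1):(npad + length(x))]
  y
}

#' Band-pass filter a clip
#'
#' Butterworth band-pass applied forward and backward (zero phase), used to
#' strip low-frequency clutter below the minimum frequency of *Carollia*
#' calls before peak-frequency screening.
#'
#' @param clip An [audio_clip()].
#' @param low_khz,high_khz Band edges, kHz; must satisfy
#'   `0 < low < high < Nyquist`.
#' @param order Butterworth order of each pass (default 4).
#' @return The filtered `audio_clip` (same length).
#' @export
bandpass <- function(clip, low_khz, high_khz, order = 4) {
  stopifnot(inherits(clip, "audio_clip"))
  nyq_khz <- clip$sample_rate_hz / 2000
  assert_scalar_number(low_khz, "low_khz")
  assert_scalar_number(high_khz, "high_khz")
  if (!(low_khz > 0 && low_khz < high_khz)) {
    stop_carollia("band edges must satisfy 0 < low_khz < high_khz")
  }
  if (high_khz >= nyq_khz) {
    stop_carollia("high_khz (", high_khz, " kHz) must be below the Nyquist ",
                  "frequency (", nyq_khz, " kHz)")
  }
  bf <- signal::butter(order, c(low_khz, high_khz) * 1000 /
                         (clip$sample_rate_hz / 2), type = "pass")
  out <- clip
  out$samples <- zero_phase_filter(bf$b, bf$a, clip$samples)
  out
}

#' Welch power spectral density of a clip
#'
#' Averaged modified periodogram: 1024-sample Hann segments with 50% overlap
#' (about 250 Hz resolution at a 256 kHz sampling rate, with stable averaging
#' over a 10-s clip). Clips shorter than one segment fall back to a single
#' periodogram of the full clip, with a message.
#'
#' @param clip An [audio_clip()].
#' @param nseg Segment length in samples.
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return A data frame with columns `freq_khz` and `power` (one-sided PSD,
#'   arbitrary power units).
#' @export
welch_psd <- function(clip, nseg = 1024, overlap = 0.5) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  n <- length(x)
  if (n < nseg) {
    message("clip shorter than one Welch segment (", n, " < ", nseg,
            "); falling back to a single periodogram")
    nseg <- n
  }
  hop <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / nseg))
  idx <- outer(seq_len(nseg) - 1L, starts, "+")
  M <- matrix(x[idx], nrow = nseg) * w
  # pack pairs of real segments into complex columns: for real u, v the
  # spectra separate as |U(f)|^2 + |V(f)|^2 = (|Z(f)|^2 + |Z(-f)|^2) / 2
  # with Z = fft(u + iv); this halves the FFT work on long clips
  npair <- ncol(M) %/% 2L
  acc <- numeric(nseg)
  if (npair > 0L) {
    Z <- mvfft(M[, 2L * seq_len(npair) - 1L, drop = FALSE] +
                 1i * M[, 2L * seq_len(npair), drop = FALSE])
    P <- Mod(Z)^2
    Prev <- P[c(1L, nseg:2L), , drop = FALSE]
    acc <- rowSums(P + Prev) / 2
  }
  if (ncol(M) %% 2L == 1L) {
    acc <- acc + Mod(fft(M[, ncol(M)]))^2
  }
  nkeep <- nseg %/% 2 + 1L
  psd <- acc[seq_len(nkeep)] / ncol(M)
  scale <- c(1, rep(2, nkeep - 2L), if (nseg %% 2L == 0L) 1 else 2)
  psd <- psd * scale / (sum(w^2) * clip$sample_rate_hz)
  data.frame(freq_khz = (seq_len(nkeep) - 1) * clip$sample_rate_hz /
               nseg / 1000,
             power = psd)
}

#' Peak frequency of a clip
#'
#' Frequency at the maximum of the Welch power spectral density estimate of
#' the full clip (the quantity the screening decision is made on). The DC bin
#' is excluded.
#'
#' @inheritParams welch_psd
#' @return Peak frequency in kHz.
#' @export
peak_frequency <- function(clip, nseg = 1024, overlap = 0.5) {
  psd <- welch_psd(clip, nseg = nseg, overlap = overlap)
  psd <- psd[psd$freq_khz > 0, ]
  psd$freq_khz[which.max(psd$power)]
}

#' Screen one clip for bat presence
#'
#' One pass of the screening algorithm: band-pass the clip with the run's
#' Butterworth band, take the Welch peak frequency of the filtered signal,
#' and flag the clip as bat-positive when that peak falls inside the run's
#' *Carollia* peak-frequency decision window.
#'
#' @param clip An [audio_clip()].
#' @param run A [run_parameters()] object.
#' @param order Butterworth order passed to [bandpass()].
#' @return A one-row data frame (class `screen_result`) with `clip_id`,
#'   `peak_frequency_khz`, `bat_positive` and `run_label`.
#' @export
screen_clip <- function(clip, run, order = 4) {
  stopifnot(inherits(run, "run_parameters"))
  filtered <- bandpass(clip, run$highpass_khz, run$lowpass_khz, order = order)
  pk <- peak_frequency(filtered)
  out <- data.frame(clip_id = clip$clip_id,
                    peak_frequency_khz = pk,
                    bat_positive = pk >= run$peak_window_khz[1] &
                      pk <= run$peak_window_khz[2],
                    run_label = run$label)
  class(out) <- c("screen_result", class(out))
  out
}

#' Two-pass screening over a set of clips
#'
#' Runs the screening algorithm twice over the clip set -- once with specific
#' parameters (type I error control) and once with sensitive parameters
#' (type II error control) -- and assembles the review queue for manual
#' spectrogram vetting as the union of the positives of both runs, each entry
#' tagged with which run(s) flagged it.
#'
#' @param clips List of [audio_clip()] objects.
#' @param run_spec,run_sens The two [run_parameters()] sets; defaults
#'   [run_specific()] and [run_sensitive()].
#' @return A list with `results` (per clip x run `screen_result` rows) and
#'   `review_queue` (one row per flagged clip with logical columns named
#'   after the two run labels).
#' @export
two_pass_screen <- function(clips, run_spec = run_specific(),
                            run_sens = run_sensitive()) {
  stopifnot(is.list(clips))
  if (identical(run_spec, run_sens)) {
    stop_carollia("the two runs must use distinct parameters")
  }
  if (length(clips) == 0L) {
    res <- data.frame(clip_id = character(), peak_frequency_khz = numeric(),
                      bat_positive = logical(), run_label = character())
  } else {
    res <- do.call(rbind, unlist(lapply(clips, function(cl) {
      list(screen_clip(cl, run_spec), screen_clip(cl, run_sens))
    }), recursive = FALSE))
  }
  pos <- res[res$bat_positive, , drop = FALSE]
  ids <- unique(pos$clip_id)
  queue <- data.frame(clip_id = ids)
  for (lab in c(run_spec$label, run_sens$label)) {
    queue[[lab]] <- ids %in% pos$clip_id[pos$run_label == lab]
  }
  list(results = res, review_queue = queue)
}
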