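#' Short-time spectrogram of a clip
#'
#' Hann-windowed short-time power spectrogram with the settings used for
#' manual call vetting: 512-point FFT and 95% overlap. The hop size
#' `nfft * (1 - overlap)` is rounded down to a whole number of samples
#' (25.6 -> 25 at 256 kHz), fixed this way for bit-reproducibility.
#' One-sided power is energy-preserving: non-DC/non-Nyquist bins carry twice
#' the FFT power so that `sum(power) / nfft` equals the total windowed-frame
#' energy.
#'
#' @param clip An [audio_clip()].
#' @param nfft FFT length (default 512).
#' @param overlap Fractional window overlap (default 0.95).
#' @return An object of class `bat_spectrogram`: a list with `power`
#'   (frequency x time matrix), `freq_khz`, `time_s` (frame centers),
#'   `hop`, `nfft`, `sample_rate_hz` and `window` (the Hann taper).
#' @export
clip_spectrogram <- function(clip, nfft = 512, overlap = 0.95) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  n <- length(x)
  if (n < nfft) {
    stop_carollia("clip (", n, " samples) is shorter than one FFT frame (",
                  nfft, ")")
  }
  hop <- max(1L, as.integer(floor(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nfft) - 1) / nfft))
  idx <- outer(seq_len(nfft) - 1L, starts, "+")
  M <- matrix(x[idx], nrow = nfft) * w
  P <- Mod(mvfft(M))^2
  nkeep <- nfft %/% 2 + 1L
  P <- P[seq_len(nkeep), , drop = FALSE]
  scale <- c(1, rep(2, nkeep - 2L), if (nfft %% 2L == 0L) 1 else 2)
  P <- P * scale
  structure(list(power = P,
                 freq_khz = (seq_len(nkeep) - 1) * clip$sample_rate_hz /
                   nfft / 1000,
                 time_s = (starts - 1 + nfft / 2) / clip$sample_rate_hz,
                 hop = hop, nfft = nfft,
                 sample_rate_hz = clip$sample_rate_hz,
                 window = w),
            class = "bat_spectrogram")
}

#' @export
print.bat_spectrogram <- function(x, ...) {
  cat(sprintf("<bat_spectrogram: %d bins x %d frames, hop %d samples>\n",
              nrow(x$power), ncol(x$power), x$hop))
  invisible(x)
}

# Per-bin noise floor: median power over time (robust to sparse calls).
noise_floor <- function(spg) {
  apply(spg$power, 1L, median)
}

#' Segment candidate calls in a spectrogram
#'
#' Finds time intervals where the summed in-band power exceeds a robust
#' noise floor (median plus `k_mad` MADs of the per-frame band energy) for at
#' least a minimum duration. Nearby exceedances are merged. The default band
#' starts at 40 kHz: calls below that are not noted, which keeps the cluttered
#' low-frequency range and most non-*Carollia* species out of the analysis.
#'
#' @param spg A [clip_spectrogram()].
#' @param band_khz Length-2 analysis band, kHz (default `c(40, 110)`).
#' @param k_mad Threshold in MAD units above the median frame energy.
#' @param min_dur_ms Minimum interval duration, ms.
#' @param merge_gap_ms Exceedance runs closer than this are merged, ms.
#' @return A data frame with one row per detected interval: `start_s`,
#'   `end_s`, `start_frame`, `end_frame`. May have zero rows.
#' @export
segment_calls <- function(spg, band_khz = c(40, 110), k_mad = 6,
                          min_dur_ms = 0.5, merge_gap_ms = 1) {
  stopifnot(inherits(spg, "bat_spectrogram"))
  inband <- spg$freq_khz >= band_khz[1] & spg$freq_khz <= band_khz[2]
  e <- colSums(spg$power[inband, , drop = FALSE])
  thr <- median(e) + k_mad * mad(e)
  active <- e > thr
  frame_ms <- spg$hop / spg$sample_rate_hz * 1000
  gap_frames <- max(1L, round(merge_gap_ms / frame_ms))
  min_frames <- max(1L, round(min_dur_ms / frame_ms))
  r <- rle(active)
  # merge short inactive gaps between active runs
  if (length(r$lengths) > 2L) {
    inner <- seq(2L, length(r$lengths) - 1L)
    fill <- inner[!r$values[inner] & r$lengths[inner] <= gap_frames]
    if (length(fill)) {
      r$values[fill] <- TRUE
      active <- inverse.rle(r)
      r <- rle(active)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  out <- data.frame(start_frame = starts[keep], end_frame = ends[keep])
  out$start_s <- spg$time_s[out$start_frame] - (spg$nfft / 2) /
    spg$sample_rate_hz
  out$end_s <- spg$time_s[out$end_frame] + (spg$nfft / 2) /
    spg$sample_rate_hz
  out[, c("start_s", "end_s", "start_frame", "end_frame")]
}

# Parabolic interpolation of a spectral peak on log power; returns the
# sub-bin offset in [-0.5, 0.5].
parabolic_offset <- function(pm1, p0, pp1) {
  lp <- log(pmax(c(pm1, p0, pp1), .Machine$double.xmin))
  den <- lp[1] - 2 * lp[2] + lp[3]
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (lp[1] - lp[3]) / den
  max(min(off, 0.5), -0.5)
}

# Spectral peaks of one frame: local maxima at least `floor_db` above the
# per-bin noise floor and within rel_db of the frame maximum. Returns a data
# frame (freq_khz, power).
frame_peaks <- function(p, freq_khz, floor_p, rel_db = 25, floor_db = 8) {
  ex <- pmax(p - floor_p, 0)
  ex[p < floor_p * 10^(floor_db / 10)] <- 0
  if (all(ex == 0)) return(NULL)
  thr <- max(ex) * 10^(-rel_db / 10)
  nb <- length(ex)
  loc <- which(ex > thr &
                 ex >= c(-Inf, ex[-nb]) &
                 ex >= c(ex[-1], -Inf))
  loc <- loc[loc > 1L & loc < nb]
  if (!length(loc)) return(NULL)
  df <- freq_khz[2] - freq_khz[1]
  fr <- vapply(loc, function(i)
    freq_khz[i] + df * parabolic_offset(ex[i - 1], ex[i], ex[i + 1]),
    numeric(1))
  data.frame(freq_khz = fr, power = ex[loc])
}

#' Measure acoustic parameters of a segmented call
#'
#' Computes the standard call parameters on a spectrogram interval:
#' call duration (ms), 90% call duration (central 90%-energy time span),
#' minimum/maximum frequency at a relative power threshold, peak frequency,
#' 95% frequency, delta frequency (`fmax - fmin`) and 90% bandwidth (span
#' between the 5% and 95% energy frequencies), together with the harmonic
#' structure. Harmonics are detected as per-frame spectral peaks lying near
#' integer multiples (within ±10%) of the lowest track; the main harmonic is
#' the one with the highest peak amplitude, and all frequency parameters are
#' measured on the main harmonic, mirroring how reference calls are measured
#' on spectrograms.
#'
#' @param spg A [clip_spectrogram()].
#' @param interval One row of [segment_calls()] output (or any list with
#'   `start_frame` and `end_frame`).
#' @param band_khz Frequencies below this floor are ignored (default 20 kHz:
#'   wind/vegetation clutter lives below it, *Carollia* fundamentals above).
#' @param support_db Relative power threshold (dB below the call's spectral
#'   maximum) defining the frequency support for `fmin`/`fmax`.
#' @param harmonic_tol Relative tolerance for matching a track to an integer
#'   multiple of the fundamental (default 0.1).
#' @return An object of class `call_measurement`: duration_ms, duration90_ms,
#'   fmin_khz, fmax_khz, fpeak_khz, f95_khz, delta_f_khz, bw90_khz,
#'   n_harmonics, main_harmonic_index, snr_db, plus the `main_track` data
#'   frame (`time_s`, `freq_khz`, `power`) used for shape classification and
#'   a `degenerate` flag for single-frame intervals.
#' @export
measure_call <- function(spg, interval, band_khz = 20, support_db = 20,
                         harmonic_tol = 0.1) {
  stopifnot(inherits(spg, "bat_spectrogram"))
  i0 <- interval$start_frame
  i1 <- interval$end_frame
  if (is.null(i0) || is.null(i1) || i0 < 1L || i1 > ncol(spg$power) ||
      i0 > i1) {
    stop_carollia("interval does not lie within the spectrogram")
  }
  degenerate <- i1 == i0
  cols <- i0:i1
  keep <- spg$freq_khz >= band_khz
  fk <- spg$freq_khz[keep]
  floor_p <- noise_floor(spg)[keep]
  P <- spg$power[keep, cols, drop = FALSE]
  X <- pmax(P - floor_p, 0)

  # --- harmonic tracks from per-frame spectral peaks ---------------------
  peaks <- lapply(seq_along(cols), function(j)
    frame_peaks(P[, j], fk, floor_p))
  hmap <- list()
  for (j in seq_along(peaks)) {
    pk <- peaks[[j]]
    if (is.null(pk)) next
    f0 <- min(pk$freq_khz)
    h <- round(pk$freq_khz / f0)
    ok <- h >= 1 & abs(pk$freq_khz - h * f0) <= harmonic_tol * h * f0
    for (i in which(ok)) {
      key <- as.character(h[i])
      hmap[[key]] <- rbind(hmap[[key]],
                           data.frame(frame = j,
                                      time_s = spg$time_s[cols[j]],
                                      freq_khz = pk$freq_khz[i],
                                      power = pk$power[i]))
    }
  }
  n_frames_pk <- sum(!vapply(peaks, is.null, TRUE))
  present <- names(hmap)[vapply(hmap, nrow, 0L) >= max(1, n_frames_pk / 2)]
  if (!length(present)) {
    # no track at all (pure noise interval); treat the whole band as one track
    present <- "1"
    hmap[["1"]] <- data.frame(frame = seq_along(cols),
                              time_s = spg$time_s[cols],
                              freq_khz = fk[max.col(t(X), "first")],
                              power = apply(X, 2, max))
  }
  n_harmonics <- length(present)
  med_power <- vapply(present, function(k) median(hmap[[k]]$power), numeric(1))
  main_key <- present[which.max(med_power)]
  main_harmonic_index <- as.integer(main_key)
  main_track <- hmap[[main_key]]
  # drop envelope-tail frames whose peak power sits >30 dB below the track
  # maximum; their frequency estimates are noise-driven
  main_track <- main_track[main_track$power >=
                             max(main_track$power) * 1e-3, , drop = FALSE]

  # --- restrict spectral measures to the main harmonic's band ------------
  df <- fk[2] - fk[1]
  lo <- min(main_track$freq_khz) - 2 * df
  hi <- max(main_track$freq_khz) + 2 * df
  rows <- fk >= lo & fk <= hi
  Xm <- X[rows, , drop = FALSE]
  fkm <- fk[rows]

  spec_energy <- rowSums(Xm)
  pk_bin <- which.max(spec_energy)
  support <- spec_energy >= spec_energy[pk_bin] * 10^(-support_db / 10) &
    spec_energy > 0
  sup_idx <- which(support)
  fmin <- fkm[min(sup_idx)]
  fmax <- fkm[max(sup_idx)]
  fpeak <- fkm[pk_bin]
  # energy percentiles over the supported bins only, so that the 90%
  # bandwidth is contained in [fmin, fmax] by construction
  es <- spec_energy[sup_idx]
  cs <- cumsum(es) / sum(es)
  f05 <- fkm[sup_idx[which(cs >= 0.05)[1]]]
  f95 <- fkm[sup_idx[which(cs >= 0.95)[1]]]

  frame_ms <- spg$hop / spg$sample_rate_hz * 1000
  duration_ms <- length(cols) * frame_ms
  te <- colSums(Xm)
  if (sum(te) > 0) {
    ct <- cumsum(te) / sum(te)
    j05 <- which(ct >= 0.05)[1]
    j95 <- which(ct >= 0.95)[1]
    duration90_ms <- (j95 - j05 + 1) * frame_ms
  } else {
    duration90_ms <- duration_ms
  }

  main_rows <- fk >= lo & fk <= hi
  snr_db <- 10 * log10(max(median(main_track$power), .Machine$double.xmin) /
                         max(median(floor_p[main_rows]),
                             .Machine$double.xmin))

  structure(list(duration_ms = duration_ms,
                 duration90_ms = min(duration90_ms, duration_ms),
                 fmin_khz = fmin, fmax_khz = fmax, fpeak_khz = fpeak,
                 f95_khz = f95, delta_f_khz = fmax - fmin,
                 bw90_khz = f95 - f05,
                 n_harmonics = n_harmonics,
                 main_harmonic_index = main_harmonic_index,
                 snr_db = snr_db,
                 main_track = main_track,
                 degenerate = degenerate),
            class = "call_measurement")
}

#' @export
print.call_measurement <- function(x, ...) {
  cat(sprintf(paste0("<call_measurement: %.2f ms, %.1f-%.1f kHz, peak %.1f",
                     " kHz, %d harmonic(s), main #%d, SNR %.1f dB>\n"),
              x$duration_ms, x$fmin_khz, x$fmax_khz, x$fpeak_khz,
              x$n_harmonics, x$main_harmonic_index, x$snr_db))
  invisible(x)
}

# Instantaneous-frequency slopes (kHz/ms) of the main track by local linear
# fits over a sliding window.
track_slopes <- function(track, window_ms = 0.7) {
  n <- nrow(track)
  if (n < 3L) return(rep(0, n))
  t_ms <- track$time_s * 1000
  half <- window_ms / 2
  vapply(seq_len(n), function(i) {
    j <- which(abs(t_ms - t_ms[i]) <= half)
    if (length(j) < 2L) return(0)
    stats::cov(t_ms[j], track$freq_khz[j]) / max(var(t_ms[j]), 1e-12)
  }, numeric(1))
}

#' Classify a measured call
#'
#' Decision tree over the measured parameters and the main-track shape.
#' Calls with maximum frequency below 40 kHz are discarded (returned as
#' `NA`): they are not noted, to keep clutter and lower-frequency species
#' out. Calls in a dense terminal train (inter-call interval below
#' `buzz_ici_ms`) are feeding buzzes. Otherwise the main track's
#' instantaneous-frequency slope splits the call into FM / QCF / CF
#' segments: constant-frequency-dominated shapes map to `FM_CF_FM`,
#' `FM_CF` or `FM_QCF` (the insectivore types), and plain FM calls are
#' labelled `FM_HARMONIC_CAROLLIA` when they carry at least `min_harmonics`
#' harmonics, the main-harmonic peak lies in the configured *Carollia*
#' window, and the main-harmonic SNR is high; FM calls with harmonics
#' failing the window or SNR rule become `FM_HARMONIC_OTHER`, and
#' single-track FM calls `FM_NO_HARMONIC`.
#'
#' @param m A [measure_call()] result.
#' @param carollia_window_khz Peak-frequency window for the *Carollia* rule
#'   (default `c(60, 80)`).
#' @param min_harmonics Minimum number of harmonics for a *Carollia* label
#'   (default 2; a single-harmonic FM call could be a different species).
#' @param snr_min_db Minimum main-harmonic SNR for a *Carollia* label, dB.
#' @param fmax_min_khz Calls with `fmax` below this are discarded.
#' @param fm_slope_khz_ms,cf_slope_khz_ms Slope thresholds separating FM
#'   (|slope| above `fm_slope_khz_ms`), QCF (between) and CF (below
#'   `cf_slope_khz_ms`) segments.
#' @param ici_ms Inter-call interval to the previous call in the sequence,
#'   ms (`NA` when unknown).
#' @param buzz_ici_ms Trains with intervals below this are feeding buzzes.
#' @return A single character: one of `"FM_NO_HARMONIC"`,
#'   `"FM_HARMONIC_CAROLLIA"`, `"FM_HARMONIC_OTHER"`, `"FM_CF_FM"`,
#'   `"FM_CF"`, `"FM_QCF"`, `"FEEDING_BUZZ"`, or `NA` for discarded calls.
#' @export
classify_call <- function(m, carollia_window_khz = c(60, 80),
                          min_harmonics = 2L, snr_min_db = 10,
                          fmax_min_khz = 40, fm_slope_khz_ms = 2.5,
                          cf_slope_khz_ms = 0.25, ici_ms = NA,
                          buzz_ici_ms = 6) {
  stopifnot(inherits(m, "call_measurement"))
  if (!is.na(ici_ms) && ici_ms < buzz_ici_ms) return("FEEDING_BUZZ")
  if (m$fmax_khz < fmax_min_khz) return(NA_character_)
  tr <- m$main_track
  n <- nrow(tr)
  sl <- abs(track_slopes(tr))
  lab <- ifelse(sl >= fm_slope_khz_ms, "FM",
                ifelse(sl >= cf_slope_khz_ms, "QCF", "CF"))
  # regression slope (kHz/ms) over a set of track frames
  fit_slope <- function(j) {
    if (length(j) < 3L) return(NA_real_)
    t_ms <- tr$time_s[j] * 1000
    stats::cov(t_ms, tr$freq_khz[j]) / max(var(t_ms), 1e-12)
  }
  longest_run <- function(keep) {
    r <- rle(keep)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    i <- which(r$values)[which.max(r$lengths[r$values])]
    (ends[i] - r$lengths[i] + 1L):ends[i]
  }
  cf_run <- longest_run(lab == "CF")
  if (!is.null(cf_run) && length(cf_run) >= 0.3 * n) {
    pre <- seq_len(min(cf_run) - 1L)
    post <- if (max(cf_run) < n) (max(cf_run) + 1L):n else integer(0)
    fm_pre <- length(pre) >= 3L &&
      isTRUE(abs(fit_slope(pre)) >= 0.5 * fm_slope_khz_ms)
    fm_post <- length(post) >= 3L &&
      isTRUE(abs(fit_slope(post)) >= 0.5 * fm_slope_khz_ms)
    return(if (fm_pre && fm_post) "FM_CF_FM" else "FM_CF")
  }
  qcf_run <- longest_run(lab != "FM")
  if (!is.null(qcf_run) && length(qcf_run) >= 0.4 * n) {
    s <- abs(fit_slope(qcf_run))
    if (isTRUE(s < fm_slope_khz_ms)) return("FM_QCF")
  }
  if (m$n_harmonics >= min_harmonics) {
    in_window <- m$fpeak_khz >= carollia_window_khz[1] &
      m$fpeak_khz <= carollia_window_khz[2]
    if (in_window && m$snr_db >= snr_min_db) return("FM_HARMONIC_CAROLLIA")
    return("FM_HARMONIC_OTHER")
  }
  "FM_NO_HARMONIC"
}
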