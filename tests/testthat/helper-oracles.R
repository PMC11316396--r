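# Independent brute-force oracles used across the suite. These are written
# against first principles (direct loops, closed forms, enumeration) and
# deliberately avoid the package's own code paths.

# Averaged modified periodogram coded as an explicit loop over segments.
oracle_peak_frequency <- function(x, fs, nseg = 1024, overlap = 0.5) {
  hop <- floor(nseg * (1 - overlap))
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / nseg))
  nkeep <- nseg %/% 2 + 1
  acc <- numeric(nkeep)
  count <- 0
  start <- 1
  while (start + nseg - 1 <= length(x)) {
    seg <- x[start:(start + nseg - 1)] * w
    sp <- abs(fft(seg))^2
    acc <- acc + sp[1:nkeep]
    count <- count + 1
    start <- start + hop
  }
  psd <- acc / count
  freqs <- (0:(nkeep - 1)) * fs / nseg
  freqs <- freqs[-1]
  psd <- psd[-1]
  freqs[which.max(psd)] / 1000    # kHz
}

# Exact conditional p-value of the Pearson statistic for a 2x2 table with
# both margins fixed, by full enumeration of the hypergeometric support.
oracle_exact_chisq_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  pearson <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }
  obs <- pearson(tab)
  p <- 0
  for (a in max(0, rs[1] + cs[1] - N):min(rs[1], cs[1])) {
    m <- matrix(c(a, rs[1] - a, cs[1] - a, N - rs[1] - cs[1] + a), 2, 2)
    if (pearson(m) >= obs - 1e-9) {
      p <- p + dhyper(a, cs[1], N - cs[1], rs[1])
    }
  }
  p
}

# Shapiro-Wilk W from the published approximation coefficients (normal
# order-statistic scores with the polynomial end corrections), coded
# independently of stats::shapiro.test.
oracle_shapiro_w <- function(x) {
  x <- sort(x); n <- length(x)
  m <- qnorm((1:n - 3 / 8) / (n + 1 / 4))
  c_ <- m / sqrt(sum(m^2))
  u <- 1 / sqrt(n)
  an <- c_[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
    4.434685 * u^4 - 2.706056 * u^5
  an1 <- c_[n - 1] + 0.042981 * u - 0.293762 * u^2 - 1.752461 * u^3 +
    5.682633 * u^4 - 3.582633 * u^5
  phi <- (sum(m^2) - 2 * m[n]^2 - 2 * m[n - 1]^2) /
    (1 - 2 * an^2 - 2 * an1^2)
  a <- m / sqrt(phi)
  a[n] <- an; a[1] <- -an; a[n - 1] <- an1; a[2] <- -an1
  sum(a * x)^2 / sum((x - mean(x))^2)
}

# Blomberg's K by explicit matrix algebra on the tree covariance matrix.
oracle_blomberg_k <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- nrow(C)
  Ci <- solve(C)
  ones <- rep(1, n)
  ahat <- as.numeric((t(ones) %*% Ci %*% x) / (t(ones) %*% Ci %*% ones))
  r <- x - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% Ci %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

# Event tally by a direct per-row loop (no vectorized grouping).
oracle_tally <- function(events, group_col) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    g <- as.character(events[[group_col]][i])
    if (is.null(out[[g]])) {
      out[[g]] <- c(bat_fruit_collections = 0, bat_visitations = 0,
                    other_visitations = 0)
    }
    bat <- tolower(events$visitor_taxon[i]) == "bat"
    b <- events$behavior[i]
    if (bat && b == "remove_fruit") {
      out[[g]]["bat_fruit_collections"] <- out[[g]]["bat_fruit_collections"] + 1
    } else if (bat && b %in% c("flyby_visit", "inspect_fruit")) {
      out[[g]]["bat_visitations"] <- out[[g]]["bat_visitations"] + 1
    } else if (!bat) {
      out[[g]]["other_visitations"] <- out[[g]]["other_visitations"] + 1
    }
  }
  out
}

# Short synthetic fixtures used by several acoustics tests (cheap clips).
make_test_clip <- function(freqs_khz, amps = rep(1, length(freqs_khz)),
                           fs = 256000, dur_s = 0.2) {
  t <- seq(0, dur_s, by = 1 / fs)
  x <- numeric(length(t))
  for (i in seq_along(freqs_khz)) {
    x <- x + amps[i] * sin(2 * pi * freqs_khz[i] * 1000 * t)
  }
  audio_clip(x, fs, clip_id = "tone")
}
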