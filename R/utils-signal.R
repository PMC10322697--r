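## Low-level signal helpers shared by the spectral and timecourse stages.

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Welch power spectral density of one or more channels
#'
#' Averaged periodogram with Hann windows, constant detrend per window and
#' one-sided density scaling. With `fs = 1200` and 1 s windows the bin
#' spacing is exactly 1 Hz.
#'
#' @param x numeric vector or samples-by-channels matrix.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds (default 1).
#' @param overlap fractional window overlap (default 0.5).
#' @param fmax highest frequency (Hz) retained.
#' @return list with `freq` (Hz, from the bin spacing up to `fmax`) and
#'   `psd` (frequencies-by-channels matrix of power density).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5, fmax = 300) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  nwin <- round(window_s * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  n <- nrow(x)
  if (n < nwin) abort("epoch shorter than the Welch window", class = "motormapr_short_epoch")
  nseg <- (n - nwin) %/% hop + 1L
  w <- hann_window(nwin)
  u <- sum(w^2)
  acc <- matrix(0, nwin, ncol(x))
  for (s in seq_len(nseg)) {
    idx <- ((s - 1L) * hop + 1L):((s - 1L) * hop + nwin)
    seg <- x[idx, , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))  # constant detrend
    X <- stats::mvfft(seg * w)
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  acc <- acc / nseg
  # one-sided: double everything except DC and (even n) Nyquist
  half <- nwin %/% 2
  ps <- acc[seq_len(half + 1L), , drop = FALSE]
  ps[2:half, ] <- 2 * ps[2:half, ]
  freq <- (0:half) * fs / nwin
  keep <- freq > 0 & freq <= fmax
  list(freq = freq[keep], psd = ps[keep, , drop = FALSE])
}

# analytic signal via FFT (Marple construction)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Gaussian smoothing with reflected edges; FFT convolution for long series
gaussian_smooth <- function(x, fs, sd_s) {
  if (sd_s <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_s * fs))
  k <- dnorm(seq(-half, half) / (fs * sd_s))
  k <- k / sum(k)
  n <- length(x)
  hh <- min(half, n)
  xp <- c(rev(x[seq_len(hh)]), x, rev(x[n - seq_len(hh) + 1L]))
  if (hh < half) {  # very short series: pad further with edge values
    xp <- c(rep(xp[1], half - hh), xp, rep(xp[length(xp)], half - hh))
  }
  r <- stats::convolve(xp, rev(k), type = "open")
  r[(2L * half + 1L):(2L * half + n)]
}

# raised-cosine fade-in/out over the first and last taper_s seconds; kills
# residual filter-edge clicks before envelope extraction
edge_taper <- function(x, fs, taper_s = 1) {
  n <- length(x)
  r <- min(round(taper_s * fs), n %/% 2)
  if (r < 2) return(x)
  w <- 0.5 * (1 - cos(pi * (seq_len(r) - 0.5) / r))
  x[seq_len(r)] <- x[seq_len(r)] * w
  x[n - seq_len(r) + 1L] <- x[n - seq_len(r) + 1L] * w
  x
}

# log with a floor at the 1st percentile of positive values (guards log(0))
floor_log <- function(x) {
  pos <- x[x > 0]
  fl <- if (length(pos)) quantile(pos, 0.01, names = FALSE) else .Machine$double.eps
  log(pmax(x, fl))
}

zscore <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

# zero-phase filtering with reflection padding: suppresses the start/end
# transients filtfilt alone leaves, which otherwise explode downstream
# exponentiation steps
filtfilt_padded <- function(b, x, fs, pad_s = 1) {
  n <- length(x)
  p <- min(n - 1L, round(pad_s * fs))
  xp <- c(rev(x[seq_len(p)]), x, rev(x[n - seq_len(p) + 1L]))
  y <- signal::filtfilt(b, xp)
  y[(p + 1L):(p + n)]
}

# third-order Butterworth band-pass, zero-phase
bandpass_zerophase <- function(x, fs, lo, hi, order = 3) {
  ny <- fs / 2
  if (hi >= ny) abort(sprintf("band edge %g Hz at or above Nyquist (%g Hz)", hi, ny))
  b <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  filtfilt_padded(b, x, fs)
}

notch_zerophase <- function(x, fs, f0, half_width = 2, order = 2) {
  ny <- fs / 2
  b <- signal::butter(order, c(f0 - half_width, f0 + half_width) / ny, type = "stop")
  filtfilt_padded(b, x, fs)
}

# sliding dot product of two equal-length, mean-subtracted series over
# lags -max_lag..max_lag (samples), computed via FFT cross-correlation.
# profile[k] = sum_t a(t) * b(t + k); positive k means b lags a.
crosscorr_profile <- function(a, b, max_lag) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  a <- a - mean(a)
  b <- b - mean(b)
  nfft <- stats::nextn(n + max_lag, c(2, 3, 5))
  A <- fft(c(a, numeric(nfft - n)))
  B <- fft(c(b, numeric(nfft - n)))
  cc <- Re(fft(Conj(A) * B, inverse = TRUE)) / nfft
  # cc[k + 1] = sum_t a(t) b(t + k) for k >= 0; negative lags wrap from the end
  lags <- -max_lag:max_lag
  vals <- numeric(length(lags))
  pos <- lags >= 0
  vals[pos] <- cc[lags[pos] + 1L]
  vals[!pos] <- cc[nfft + lags[!pos] + 1L]
  list(lags = lags, profile = vals)
}
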