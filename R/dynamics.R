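#' Broadband power timecourse per sEEG channel
#'
#' For each channel: (1) band-pass with third-order Butterworth filters
#' (zero-phase) in 10 Hz bands between 65 and 115 Hz, (2) square the Hilbert
#' analytic amplitude of each band, (3) sum the bands. The summed series is
#' then logged (floored at the 1st percentile of positive values), z-scored
#' over the whole run, Gaussian-smoothed, exponentiated and centered at zero
#' by subtracting 1 — so resting output hovers around 0 and the result is
#' invariant to overall signal gain.
#'
#' @param recording a [bipolar_rereference()]d recording; `fs` must exceed
#'   twice the top band edge.
#' @param band overall band, Hz (split into `step`-wide sub-bands).
#' @param step sub-band width, Hz.
#' @param smooth_sd_s Gaussian smoothing sd, seconds (default 0.05).
#' @return object of class `timecourse`: samples-by-channels matrix plus
#'   processing metadata.
#' @export
broadband_timecourse <- function(recording, band = c(65, 115), step = 10,
                                 smooth_sd_s = 0.05) {
  fs <- recording$fs
  if (band[2] >= fs / 2) {
    abort(sprintf("sampling rate %g Hz too low for a %g Hz band edge", fs, band[2]))
  }
  edges <- seq(band[1], band[2], by = step)
  ch <- seeg_channel_names(recording)
  out <- matrix(0, nrow(recording$data), length(ch))
  colnames(out) <- ch
  for (j in seq_along(ch)) {
    x <- recording$data[, ch[j]]
    acc <- numeric(length(x))
    for (b in seq_len(length(edges) - 1L)) {
      xb <- edge_taper(bandpass_zerophase(x, fs, edges[b], edges[b + 1L]), fs)
      acc <- acc + Mod(analytic_signal(xb))^2
    }
    z <- zscore(floor_log(acc))
    out[, j] <- exp(gaussian_smooth(z, fs, smooth_sd_s)) - 1
  }
  structure(list(data = out, fs = fs,
                 band = band, step = step, smooth_sd_s = smooth_sd_s,
                 kind = "broadband"),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse:%s> %d channels x %d samples @ %g Hz\n",
              x$kind, ncol(x$data), nrow(x$data), x$fs))
  invisible(x)
}

#' Conditioned EMG envelope
#'
#' Band-passes each EMG channel 25-400 Hz (third-order Butterworth,
#' zero-phase), notch-filters the 60/120/180 Hz line harmonics, rectifies
#' (absolute value) and envelopes (Gaussian smoothing), then logs, z-scores,
#' smooths and exponentiates. Output is non-negative; an all-zero channel
#' yields a constant (the log floor guards against NaN).
#'
#' @param recording recording containing `kind = "emg"` channels.
#' @param band EMG band, Hz.
#' @param notch line frequencies to remove, Hz.
#' @param smooth_sd_s smoothing sd, seconds.
#' @param output `"normalized"` for the full chain, `"linear"` to stop after
#'   rectification and envelope smoothing — the linear envelope keeps
#'   threshold crossings symmetric around burst onsets, which onset detection
#'   relies on.
#' @return samples-by-channels matrix of envelopes (column names = channel
#'   names).
#' @export
condition_emg <- function(recording, band = c(25, 400), notch = c(60, 120, 180),
                          smooth_sd_s = 0.05,
                          output = c("normalized", "linear")) {
  output <- match.arg(output)
  fs <- recording$fs
  if (fs <= 800) abort("sampling rate too low for 25-400 Hz EMG conditioning")
  emg <- emg_channel_names(recording)
  if (!length(emg)) abort("recording has no EMG channels", class = "motormapr_no_emg")
  out <- matrix(0, nrow(recording$data), length(emg))
  colnames(out) <- emg
  for (j in seq_along(emg)) {
    x <- recording$data[, emg[j]]
    if (all(x == 0)) {  # flat channel: constant envelope, caller decides
      out[, j] <- 0
      next
    }
    x <- bandpass_zerophase(x, fs, band[1], band[2])
    for (f0 in notch) x <- notch_zerophase(x, fs, f0)
    env <- gaussian_smooth(abs(x), fs, smooth_sd_s)  # rectify then envelope
    if (output == "linear") {
      out[, j] <- env
    } else {
      z <- zscore(floor_log(env))
      out[, j] <- exp(gaussian_smooth(z, fs, smooth_sd_s))
    }
  }
  out
}

#' Event-locked average timecourse
#'
#' Averages a timecourse across the given channels and across the epochs of
#' each movement class, from `window[1]` before to `window[2]` after movement
#' onset. Each class trace is shifted to start at 0 so shapes can be compared
#' across channel groups. Epochs whose window exceeds the recording are
#' dropped with a warning.
#'
#' @param tc a [broadband_timecourse()] object.
#' @param events epoch table (movement onsets are used).
#' @param channels channel names to average (default: all).
#' @param window seconds around onset, default `c(-0.5, 4)`.
#' @return tibble: `trial_type`, `time_s`, `value`, `n_epochs`.
#' @export
event_locked_average <- function(tc, events, channels = NULL,
                                 window = c(-0.5, 4)) {
  events <- validate_events(events)
  fs <- tc$fs
  channels <- channels %||% colnames(tc$data)
  dat <- tc$data[, channels, drop = FALSE]
  i_rel <- round(window[1] * fs):round(window[2] * fs)
  res <- list()
  for (mv in setdiff(unique(events$trial_type), "rest")) {
    ons <- events$onset_s[events$trial_type == mv]
    traces <- list()
    for (o in ons) {
      idx <- round(o * fs) + i_rel + 1L
      if (idx[1] < 1 || idx[length(idx)] > nrow(dat)) {
        warn(sprintf("epoch at %.2f s exceeds the recording; dropped", o))
        next
      }
      traces[[length(traces) + 1L]] <- rowMeans(dat[idx, , drop = FALSE])
    }
    if (!length(traces)) next
    avg <- Reduce(`+`, traces) / length(traces)
    avg <- avg - avg[1]  # shift to start at 0
    res[[length(res) + 1L]] <- tibble(trial_type = mv, time_s = i_rel / fs,
                                      value = avg, n_epochs = length(traces))
  }
  dplyr::bind_rows(res)
}

#' Brain-EMG latency by sliding dot product
#'
#' Correlation profile between each sEEG channel's broadband timecourse and
#' each conditioned EMG envelope over lags of -`max_lag_s` to +`max_lag_s` in
#' one-sample steps (dot product of mean-subtracted series). Positive peak lag
#' means the brain signal precedes the EMG. Peaks at the lag boundary are
#' flagged unreliable.
#'
#' @param tc a [broadband_timecourse()] object.
#' @param emg_env envelope matrix from [condition_emg()]; the rectified linear
#'   envelope (`output = "linear"`) keeps the correlation apex symmetric.
#' @param max_lag_s lag range, seconds (default 2).
#' @param edge_trim_s seconds dropped from both ends of the run before the dot
#'   product, so start/end conditioning artifacts cannot tilt the profile.
#' @return `latency_profile` tibble: `channel`, `effector`, `lag_ms`, `peak`,
#'   `at_boundary`; the full profiles are kept in the `"profiles"` attribute.
#' @export
estimate_latency <- function(tc, emg_env, max_lag_s = 2, edge_trim_s = 2) {
  fs <- tc$fs
  if (nrow(emg_env) != nrow(tc$data)) abort("timecourse and EMG envelope lengths differ")
  max_lag <- round(max_lag_s * fs)
  n <- nrow(tc$data)
  tr <- min(round(edge_trim_s * fs), (n - 2L * max_lag - 2L) %/% 2)
  span <- (tr + 1L):(n - tr)
  rows <- list()
  profiles <- list()
  for (chn in colnames(tc$data)) {
    for (ef in colnames(emg_env)) {
      # profile(k) = sum_t bb(t) * emg(t + k): peak at k > 0 when the EMG
      # trails the brain signal by k samples, i.e. brain leads.
      cc <- crosscorr_profile(tc$data[span, chn], emg_env[span, ef], max_lag)
      i <- which.max(cc$profile)
      rows[[length(rows) + 1L]] <- tibble(
        channel = chn, effector = sub("^EMG_", "", ef),
        lag_ms = cc$lags[i] * 1000 / fs,
        peak = cc$profile[i],
        at_boundary = i == 1L || i == length(cc$profile))
      profiles[[paste(chn, ef, sep = "|")]] <- cc
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "profiles") <- profiles
  class(out) <- c("latency_profile", class(out))
  out
}
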