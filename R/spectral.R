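#' Per-trial power spectral densities
#'
#' For every epoch and every sEEG pair channel, computes a Welch PSD (1 Hz
#' bins from 1 to `fmax` Hz, 1 s Hann windows, 0.5 s overlap, constant
#' detrend) and then normalizes each trial's PSD bin-wise by the global mean
#' PSD across all trials of that channel, so that 1/f shape and per-channel
#' gain drop out. Epochs shorter than one window are skipped with a warning;
#' rest epochs shorter than 1 s are dropped.
#'
#' @param recording a [bipolar_rereference()]d recording (raw recordings with
#'   `kind = "seeg"` channels are accepted too).
#' @param events epoch table, typically from [emg_epochs()].
#' @param fmax top frequency, Hz (default 300).
#' @return object of class `trial_psd`: normalized PSD array
#'   (channel x epoch x frequency), the normalization vector, frequencies, and
#'   the epoch table (with `epoch` ids).
#' @export
trial_psd <- function(recording, events, fmax = 300) {
  events <- validate_events(events)
  fs <- recording$fs
  ch <- seeg_channel_names(recording)
  if (!length(ch)) abort("no sEEG channels to analyse")
  nwin <- round(fs)
  keep <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(events))) {
    len <- round(events$duration_s[i] * fs)
    i0 <- round(events$onset_s[i] * fs) + 1L
    if (i0 < 1 || i0 + len - 1L > nrow(recording$data)) {
      warn(sprintf("epoch %d exceeds the recording; dropped", i))
      keep[i] <- FALSE
    } else if (len < nwin) {
      warn(sprintf("epoch %d shorter than the 1 s Welch window; skipped", i))
      keep[i] <- FALSE
    }
  }
  events <- events[keep, ]
  events$epoch <- seq_len(nrow(events))
  freq <- NULL
  psd <- NULL
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$onset_s[i] * fs) + 1L
    len <- round(events$duration_s[i] * fs)
    seg <- recording$data[i0:(i0 + len - 1L), ch, drop = FALSE]
    w <- welch_psd(seg, fs, window_s = 1, overlap = 0.5, fmax = fmax)
    if (is.null(psd)) {
      freq <- w$freq
      psd <- array(NA_real_, c(length(ch), nrow(events), length(freq)),
                   dimnames = list(ch, NULL, NULL))
    }
    psd[, i, ] <- t(w$psd)
  }
  norm <- apply(psd, c(1, 3), mean)  # global mean PSD across all trials
  normalized <- aperm(array(apply(psd, 2, function(m) m / norm),
                            dim = c(length(ch), length(freq), nrow(events))),
                      c(1, 3, 2))
  structure(list(psd = normalized, norm = norm, freq = freq,
                 epochs = events, channels = ch, fs = fs),
            class = "trial_psd")
}

#' @export
print.trial_psd <- function(x, ...) {
  cat(sprintf("<trial_psd> %d channels x %d epochs x %d frequency bins (%g-%g Hz)\n",
              dim(x$psd)[1], dim(x$psd)[2], dim(x$psd)[3], min(x$freq), max(x$freq)))
  invisible(x)
}

#' Band-averaged normalized power per trial
#'
#' Mean of the normalized PSD over `band` (inclusive), by default the 65-115
#' Hz broadband high-frequency range, which sits above most oscillations and
#' between the 60 and 120 Hz line-noise harmonics.
#'
#' @param tpsd a [trial_psd()] object.
#' @param band numeric length-2, Hz.
#' @return tibble with one row per channel x epoch: `channel`, `epoch`,
#'   `trial_type`, `follows`, `power`.
#' @export
band_power <- function(tpsd, band = c(65, 115)) {
  stopifnot(inherits(tpsd, "trial_psd"))
  sel <- tpsd$freq >= band[1] & tpsd$freq <= band[2]
  if (!any(sel)) abort("band contains no frequency bins")
  bp <- apply(tpsd$psd[, , sel, drop = FALSE], c(1, 2), mean)
  tibble(
    channel = rep(tpsd$channels, times = ncol(bp)),
    epoch = rep(tpsd$epochs$epoch, each = nrow(bp)),
    trial_type = rep(tpsd$epochs$trial_type, each = nrow(bp)),
    follows = rep(tpsd$epochs$follows, each = nrow(bp)),
    power = as.numeric(bp)
  )
}

#' Signed r-squared of movement versus rest samples
#'
#' Signed coefficient of determination between two sample groups:
#' `sign(mean(m) - mean(r))` times the fraction of the pooled-sample variance
#' explained by the group split,
#' `(mean(m) - mean(r))^2 * n_m * n_r / (var_pop(pooled) * (n_m + n_r)^2)`,
#' where `var_pop` is the population (divide-by-N) variance. This equals the
#' squared point-biserial correlation between the pooled samples and the group
#' label, carrying the sign of the mean difference; it is 0 when the means are
#' equal and bounded by 1 in magnitude.
#'
#' @param m,r numeric sample vectors (each length >= 2).
#' @return scalar in \[-1, 1\].
#' @export
signed_r2 <- function(m, r) {
  nm <- length(m); nr <- length(r)
  if (nm < 2 || nr < 2) abort("need at least 2 samples per group")
  pooled <- c(m, r)
  n <- nm + nr
  v <- sum((pooled - mean(pooled))^2) / n  # population variance
  d <- mean(m) - mean(r)
  if (d == 0) return(0)
  if (v == 0) return(0)  # constant pooled input
  sign(d) * d^2 * nm * nr / (v * n^2)
}

#' Movement-versus-rest statistics per channel
#'
#' For every channel and movement type, compares the band power of that
#' movement's trials against the rest trials that followed that same movement
#' type (the pairing that avoids beta-rebound contamination of rest), giving
#' the signed r-squared and an unpaired two-sample t-test p-value.
#'
#' @param tpsd a [trial_psd()] object.
#' @param band analysis band, Hz (default broadband 65-115).
#' @param var_equal use the pooled-variance (Student) t-test (default TRUE).
#' @return `channel_stats` tibble: `channel`, `movement`, `r2`, `p`, `n_move`,
#'   `n_rest`, `mean_move`, `mean_rest`.
#' @export
movement_stats <- function(tpsd, band = c(65, 115), var_equal = TRUE) {
  bp <- band_power(tpsd, band)
  res <- list()
  for (chn in unique(bp$channel)) {
    b <- bp[bp$channel == chn, ]
    for (mv in MOVEMENTS) {
      m <- b$power[b$trial_type == mv]
      r <- b$power[b$trial_type == "rest" & !is.na(b$follows) & b$follows == mv]
      if (length(m) < 2 || length(r) < 2) {
        res[[length(res) + 1L]] <- tibble(channel = chn, movement = mv,
                                          r2 = NA_real_, p = NA_real_,
                                          n_move = length(m), n_rest = length(r),
                                          mean_move = NA_real_, mean_rest = NA_real_)
        next
      }
      res[[length(res) + 1L]] <- tibble(
        channel = chn, movement = mv,
        r2 = signed_r2(m, r),
        p = t.test(m, r, var.equal = var_equal)$p.value,
        n_move = length(m), n_rest = length(r),
        mean_move = mean(m), mean_rest = mean(r))
    }
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("channel_stats", class(out))
  out
}
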