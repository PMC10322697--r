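#' Specification for the synthetic session generator
#'
#' Defines the study conditions a generated session emulates: an interleaved
#' block task (20 cues per movement, 3 s move / 3 s rest), depth-electrode
#' channels drawn from five ground-truth classes, 1/f background spectra with
#' line noise, movement-locked broadband (65-115 Hz) power increases and
#' 10-30 Hz (beta) decreases, brain activity leading EMG by `tau_s`, and
#' rectifiable EMG bursts per effector.
#'
#' @param seed integer seed; the same spec + seed gives bit-identical output.
#' @param fs sampling rate, Hz.
#' @param n_trials_per_movement cues per movement type.
#' @param cue_s,rest_s cue and rest durations, seconds.
#' @param plan named integer vector of channel counts per class:
#'   `somatotopic_hand`, `somatotopic_tongue`, `somatotopic_foot`, `rma`,
#'   `inactive`.
#' @param g_bb broadband gain: ratio of 65-115 Hz power, movement vs rest
#'   (> 1).
#' @param g_beta beta suppression: multiplicative 10-30 Hz power factor during
#'   movement (0 < g_beta < 1).
#' @param gain_sd log-scale sd of per-(channel, movement) broadband gain
#'   heterogeneity around `g_bb`; responsive sites differ in response
#'   amplitude across movements, as real recordings do.
#' @param tau_s brain lead: seconds by which broadband modulation precedes EMG
#'   onset (>= 0).
#' @param reaction_mean_s mean cue-to-EMG reaction delay.
#' @param emg_jitter_sd EMG onset/offset jitter sd, seconds.
#' @param line_amps amplitudes (uV) of line-noise sinusoids at 60/120/180 Hz.
#' @param exponent 1/f power-law exponent of the background spectrum.
#' @param preset `"default"`, or `"beta_only"`: no broadband change
#'   (`g_bb = 1`) and nonspecific beta suppression during every movement on
#'   every non-inactive channel — the widespread low-frequency decrease
#'   regime.
#' @param pad_s silent padding before the first and after the last epoch.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           fs = 1200,
                           n_trials_per_movement = 20L,
                           cue_s = 3, rest_s = 3,
                           plan = c(somatotopic_hand = 10L, somatotopic_tongue = 10L,
                                    somatotopic_foot = 10L, rma = 6L, inactive = 30L),
                           g_bb = 3.0,
                           g_beta = 0.5,
                           gain_sd = 0.2,
                           tau_s = 0.1,
                           reaction_mean_s = 0.15,
                           emg_jitter_sd = 0.05,
                           line_amps = c(`60` = 5, `120` = 2, `180` = 1),
                           exponent = 2,
                           preset = c("default", "beta_only"),
                           pad_s = 2) {
  preset <- match.arg(preset)
  if (preset == "beta_only") g_bb <- 1.0
  default_plan <- c(somatotopic_hand = 10L, somatotopic_tongue = 10L,
                    somatotopic_foot = 10L, rma = 6L, inactive = 30L)
  plan <- as.integer(plan[names(default_plan)])
  names(plan) <- names(default_plan)
  plan[is.na(plan)] <- 0L
  if (any(plan < 0)) abort("channel counts must be >= 0")
  if (g_bb < 1) abort("g_bb must be >= 1")
  if (g_beta <= 0 || g_beta >= 1) abort("g_beta must be in (0, 1)")
  if (tau_s < 0) abort("tau_s must be >= 0")
  structure(list(seed = as.integer(seed), fs = fs,
                 n_trials_per_movement = as.integer(n_trials_per_movement),
                 cue_s = cue_s, rest_s = rest_s, plan = plan,
                 g_bb = g_bb, g_beta = g_beta, gain_sd = gain_sd,
                 tau_s = tau_s, reaction_mean_s = reaction_mean_s,
                 emg_jitter_sd = emg_jitter_sd, line_amps = line_amps,
                 exponent = exponent, preset = preset, pad_s = pad_s),
            class = "generator_spec")
}

#' Task schedule for a generated session
#'
#' Shuffles 20 cues of each movement type into seeded random order; each 3 s
#' movement cue is followed by a 3 s rest epoch tagged (`follows`) with the
#' movement type it follows, so movement trials can later be compared against
#' the rest periods that followed that same movement type.
#'
#' @param spec a [generator_spec()].
#' @return event tibble (see [validate_events()]).
#' @export
make_schedule <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed, {
    order <- sample(rep(MOVEMENTS, each = spec$n_trials_per_movement))
  })
  n <- length(order)
  block <- spec$cue_s + spec$rest_s
  onsets <- spec$pad_s + (seq_len(n) - 1) * block
  cue <- tibble(onset_s = onsets, duration_s = spec$cue_s,
                trial_type = order, source = "cue", follows = NA_character_)
  rest <- tibble(onset_s = onsets + spec$cue_s, duration_s = spec$rest_s,
                 trial_type = "rest", source = "cue", follows = order)
  validate_events(dplyr::arrange(dplyr::bind_rows(cue, rest), .data$onset_s))
}

# 1/f-shaped Gaussian noise restricted to (or excluding) frequency bands,
# built in the Fourier domain so band components of a channel are exactly
# power-additive.
colored_noise <- function(n, fs, exponent, band = NULL, exclude = NULL) {
  m <- n %/% 2
  f <- (1:m) * fs / n
  amp <- f^(-exponent / 2)
  if (!is.null(band)) amp[f < band[1] | f > band[2]] <- 0
  if (!is.null(exclude)) {
    for (b in exclude) amp[f >= b[1] & f <= b[2]] <- 0
  }
  z <- complex(real = rnorm(m), imaginary = rnorm(m)) * amp
  if (n %% 2 == 0) z[m] <- complex(real = Re(z[m]), imaginary = 0)
  full <- c(0 + 0i, z, Conj(rev(z[seq_len(m - (n %% 2 == 0))])))
  Re(fft(full, inverse = TRUE)) / sqrt(n)
}

# raised-cosine gate: 0 outside epochs, 1 inside, cosine ramps at the edges
epoch_envelope <- function(n, fs, onsets_s, offsets_s, ramp_s = 0.1) {
  env <- numeric(n)
  r <- max(2L, round(ramp_s * fs))
  ramp_up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
  for (j in seq_along(onsets_s)) {
    i0 <- round(onsets_s[j] * fs)
    i1 <- round(offsets_s[j] * fs)
    up <- (i0 - r %/% 2) + seq_len(r)
    dn <- (i1 - r %/% 2) + seq_len(r)
    core <- (max(up) + 1L):(min(dn) - 1L)
    sel <- function(idx) idx[idx >= 1 & idx <= n]
    env[sel(up)] <- pmax(env[sel(up)], ramp_up[which(up >= 1 & up <= n)])
    if (length(core) && core[1] <= core[length(core)]) env[sel(core)] <- 1
    env[sel(dn)] <- pmax(env[sel(dn)], rev(ramp_up)[which(dn >= 1 & dn <= n)])
  }
  env
}

responsive_movements <- function(class, preset) {
  switch(class,
         somatotopic_hand = "hand",
         somatotopic_tongue = "tongue",
         somatotopic_foot = "foot",
         rma = MOVEMENTS,
         inactive = character(0))
}

#' Synthesize a session with known ground truth
#'
#' Generates monopolar sEEG contacts (two per lead segment, so that adjacent
#' differential pairs recover one class-labelled analysis channel each) plus
#' three EMG channels. Each analysis channel is the sum of three independent
#' 1/f-shaped noise streams — a 10-30 Hz beta stream, a 65-115 Hz broadband
#' stream and the spectral remainder — whose gains are cross-faded with 100 ms
#' raised-cosine ramps during that channel's responsive movement epochs:
#' broadband power times `g_bb`, beta power times `g_beta`. Brain modulation
#' begins `tau_s` before EMG onset. All contacts of a lead share a common-mode
#' 7 Hz sinusoid that bipolar rereferencing removes exactly. EMG channels are
#' near-silent baselines with 25-400 Hz band-limited bursts during their
#' effector's movements, onsets jittered around the cue.
#'
#' @param spec a [generator_spec()].
#' @return list with `recording`, `events` (cue-timed), and `ground_truth`
#'   (list of per-channel `channels` and per-trial `trials` tibbles).
#' @export
synthesize_session <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  events <- make_schedule(spec)
  fs <- spec$fs
  total_s <- max(events$onset_s + events$duration_s) + spec$pad_s
  n <- round(total_s * fs)
  cues <- events[events$trial_type != "rest", ]

  withr::with_seed(spec$seed + 1L, {
    ## --- trial ground truth: EMG onset/offset jittered around the cue
    trials <- tibble(
      trial = seq_len(nrow(cues)),
      movement = cues$trial_type,
      cue_onset_s = cues$onset_s,
      cue_duration_s = cues$duration_s,
      emg_onset_s = cues$onset_s + spec$reaction_mean_s +
        rnorm(nrow(cues), 0, spec$emg_jitter_sd),
      emg_offset_s = cues$onset_s + cues$duration_s + spec$reaction_mean_s +
        rnorm(nrow(cues), 0, spec$emg_jitter_sd)
    )
    # keep bursts inside their own block
    trials$emg_onset_s <- pmax(trials$emg_onset_s, trials$cue_onset_s + 0.02)
    trials$emg_offset_s <- pmin(trials$emg_offset_s,
                                trials$cue_onset_s + trials$cue_duration_s + spec$rest_s - 0.5)

    ## --- channel plan
    classes <- sample(rep(names(spec$plan), spec$plan))
    n_pairs <- length(classes)
    if (n_pairs == 0) abort("channel plan is empty")
    pairs_per_lead <- 6L
    lead_of <- (seq_len(n_pairs) - 1L) %/% pairs_per_lead + 1L
    seg_of <- (seq_len(n_pairs) - 1L) %% pairs_per_lead + 1L

    gt_channels <- tibble(
      pair = sprintf("L%02dS%dC1-L%02dS%dC2", lead_of, seg_of, lead_of, seg_of),
      class = classes,
      responsive = vapply(classes, function(cl)
        paste(responsive_movements(cl, spec$preset), collapse = ","), character(1)),
      tau_s = ifelse(classes == "inactive", NA_real_, spec$tau_s)
    )

    ## --- per-movement brain modulation windows (brain leads EMG by tau)
    mv_windows <- lapply(MOVEMENTS, function(mv) {
      tr <- trials[trials$movement == mv, ]
      list(on = tr$emg_onset_s - spec$tau_s, off = tr$emg_offset_s - spec$tau_s)
    })
    names(mv_windows) <- MOVEMENTS
    mv_env <- lapply(MOVEMENTS, function(mv)
      epoch_envelope(n, fs, mv_windows[[mv]]$on, mv_windows[[mv]]$off, ramp_s = 0.1))
    names(mv_env) <- MOVEMENTS

    ## --- leads: common-mode 7 Hz sinusoid, identical on all contacts
    t_s <- (seq_len(n) - 1) / fs
    leads <- unique(lead_of)
    common <- lapply(leads, function(l) 30 * sin(2 * pi * 7 * t_s + runif(1, 0, 2 * pi)))
    names(common) <- as.character(leads)

    beta_band <- c(10, 30)
    bb_band <- c(65, 115)
    lf <- as.numeric(names(spec$line_amps))

    n_emg <- 3L
    data <- matrix(0, n, 2L * n_pairs + n_emg)
    ch_rows <- vector("list", 2L * n_pairs + n_emg)

    for (j in seq_len(n_pairs)) {
      rest_stream <- colored_noise(n, fs, spec$exponent, exclude = list(beta_band, bb_band))
      beta_stream <- colored_noise(n, fs, spec$exponent, band = beta_band)
      bb_stream <- colored_noise(n, fs, spec$exponent, band = bb_band)
      sc <- 20 / sd(rest_stream + beta_stream + bb_stream)

      resp_bb <- responsive_movements(classes[j], spec$preset)
      resp_beta <- if (spec$preset == "beta_only" && classes[j] != "inactive") {
        MOVEMENTS
      } else resp_bb
      bb_mult <- rep(1, n)
      for (mv in resp_bb) {
        g <- spec$g_bb * exp(rnorm(1, 0, spec$gain_sd))
        g <- max(g, 1)
        bb_mult <- bb_mult + (sqrt(g) - 1) * mv_env[[mv]]
      }
      beta_mult <- rep(1, n)
      for (mv in resp_beta) {
        beta_mult <- beta_mult + (sqrt(spec$g_beta) - 1) * mv_env[[mv]]
      }
      pair_sig <- sc * (rest_stream + beta_stream * beta_mult + bb_stream * bb_mult)
      for (i in seq_along(lf)) {
        pair_sig <- pair_sig + spec$line_amps[i] * sin(2 * pi * lf[i] * t_s + runif(1, 0, 2 * pi))
      }

      cm <- common[[as.character(lead_of[j])]]
      ia <- 2L * j - 1L
      data[, ia] <- cm + pair_sig
      # reference contact: common mode plus amplifier-scale noise, well below
      # the brain signal's high-frequency power so differencing keeps contrast
      data[, ia + 1L] <- cm + rnorm(n, 0, 0.05)
      ch_rows[[ia]] <- tibble(name = sprintf("L%02dS%dC1", lead_of[j], seg_of[j]),
                              kind = "seeg", lead_id = sprintf("L%02d", lead_of[j]),
                              segment_id = seg_of[j], contact_index = 1L)
      ch_rows[[ia + 1L]] <- tibble(name = sprintf("L%02dS%dC2", lead_of[j], seg_of[j]),
                                   kind = "seeg", lead_id = sprintf("L%02d", lead_of[j]),
                                   segment_id = seg_of[j], contact_index = 2L)
    }

    ## --- EMG channels: baseline + band-limited bursts at the jittered onsets
    for (k in seq_along(MOVEMENTS)) {
      mv <- MOVEMENTS[k]
      tr <- trials[trials$movement == mv, ]
      burst_env <- epoch_envelope(n, fs, tr$emg_onset_s, tr$emg_offset_s, ramp_s = 0.02)
      burst <- colored_noise(n, fs, exponent = 0, band = c(25, 400))
      burst <- burst / sd(burst) * 10
      col <- 2L * n_pairs + k
      data[, col] <- rnorm(n, 0, 1) + burst * burst_env
      ch_rows[[col]] <- tibble(name = paste0("EMG_", mv), kind = "emg",
                               lead_id = NA_character_, segment_id = NA_integer_,
                               contact_index = k)
    }
  })

  channels <- dplyr::bind_rows(ch_rows)
  rec <- new_recording(data, fs = fs, channels = channels)
  list(recording = rec, events = events,
       ground_truth = list(channels = gt_channels, trials = trials, spec = spec))
}
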