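#' Bipolar rereferencing of depth-electrode contacts
#'
#' Forms differential pair channels from adjacent contacts (contact index
#' difference of 1) on the same lead segment; segmented leads are never paired
#' across segments. The pair signal is `proximal - distal`
#' (contact i minus contact i+1); the pair position is the interpolated
#' midpoint of the two contacts. Rereferencing removes any signal common to
#' both contacts exactly. EMG channels pass through untouched.
#'
#' @param recording a [new_recording()] object with >= 2 seeg contacts on some
#'   lead segment.
#' @return a `bipolar_recording` (subclass of `seeg_recording`) whose channel
#'   table has `kind = "seeg_pair"` rows carrying `name_a`/`name_b`.
#' @export
bipolar_rereference <- function(recording) {
  stopifnot(inherits(recording, "seeg_recording"))
  ch <- recording$channels
  seeg <- ch[ch$kind == "seeg", ]
  groups <- split(seq_len(nrow(seeg)), interaction(seeg$lead_id, seeg$segment_id, drop = TRUE))
  pair_rows <- list()
  for (g in groups) {
    g <- g[order(seeg$contact_index[g])]
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1L)) {
      a <- seeg[g[i], ]; b <- seeg[g[i + 1L], ]
      if (b$contact_index - a$contact_index != 1L) next  # non-adjacent contacts
      pair_rows[[length(pair_rows) + 1L]] <- tibble(
        name = paste0(a$name, "-", b$name),
        kind = "seeg_pair",
        lead_id = a$lead_id, segment_id = a$segment_id,
        contact_index = a$contact_index,
        name_a = a$name, name_b = b$name,
        x = (a$x + b$x) / 2, y = (a$y + b$y) / 2, z = (a$z + b$z) / 2)
    }
  }
  if (!length(pair_rows)) {
    abort("no adjacent contact pairs found on any lead segment",
          class = "motormapr_no_pairs")
  }
  pairs <- dplyr::bind_rows(pair_rows)
  pd <- recording$data[, pairs$name_a, drop = FALSE] -
    recording$data[, pairs$name_b, drop = FALSE]
  colnames(pd) <- pairs$name
  emg <- ch[ch$kind == "emg", ]
  if (nrow(emg)) {
    pd <- cbind(pd, recording$data[, emg$name, drop = FALSE])
    emg$name_a <- NA_character_; emg$name_b <- NA_character_
    pairs <- dplyr::bind_rows(pairs, emg)
  }
  out <- list(data = pd, fs = recording$fs, channels = pairs)
  class(out) <- c("bipolar_recording", "seeg_recording")
  out
}

seeg_channel_names <- function(rec) {
  rec$channels$name[rec$channels$kind %in% c("seeg", "seeg_pair")]
}

emg_channel_names <- function(rec) {
  rec$channels$name[rec$channels$kind == "emg"]
}

# Detect onset/offset of one supra-threshold EMG burst near a cue.
# Coarse gate: conditioned envelope above mean + 3 sd of baseline for a
# sustained run; fine timing: half-maximum crossing of that run, which is
# unbiased under symmetric smoothing.
detect_burst <- function(env, fs, win_lo, win_hi, thr, min_dur_s = 0.2) {
  i0 <- max(1L, round(win_lo * fs)); i1 <- min(length(env), round(win_hi * fs))
  seg <- env[i0:i1]
  above <- seg > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= round(min_dur_s * fs))
  if (!length(ok)) return(NULL)
  a <- starts[ok[1]]; b <- ends[ok[length(ok)]]
  base_level <- median(seg[!above])
  if (!is.finite(base_level)) base_level <- thr
  half <- (max(seg[a:b]) + base_level) / 2
  on <- a; while (on < b && seg[on] < half) on <- on + 1L
  off <- b; while (off > a && seg[off] < half) off <- off - 1L
  c(onset = (i0 + on - 2L) / fs, offset = (i0 + off - 1L) / fs)
}

#' Re-time movement epochs to EMG onset and offset
#'
#' Movement timing is taken from the muscle, not the visual cue: each cue's
#' epoch is re-timed to the onset/offset of the conditioned EMG envelope of
#' that effector (threshold: baseline mean + 3 sd sustained for
#' `min_duration_s`, refined to the half-maximum crossing). Rest epochs keep
#' their `follows` tag; a rest epoch's start moves to the preceding EMG offset
#' when movement outlasts the cue. Effectors with no EMG channel fall back to
#' cue epochs shifted by the mean cue-to-EMG delay of the detected effectors
#' (with a message).
#'
#' @param recording the (monopolar) recording holding the EMG channels.
#' @param events cue-timed events.
#' @param threshold_sd baseline multiple for the coarse gate (default 3).
#' @param min_duration_s minimum sustained supra-threshold time (default 0.2).
#' @param search_pad_s how far outside the cue to search, seconds.
#' @return event tibble with `source = "emg"`.
#' @export
emg_epochs <- function(recording, events, threshold_sd = 3,
                       min_duration_s = 0.2, search_pad_s = 0.5) {
  events <- validate_events(events)
  fs <- recording$fs
  emg_names <- emg_channel_names(recording)
  cues <- events[events$trial_type != "rest", ]
  effectors <- unique(cues$trial_type)
  env <- condition_emg(recording, output = "linear")

  find_channel <- function(mv) {
    hit <- grep(mv, emg_names, ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }

  out <- cues
  out$source <- "emg"
  delays_on <- c(); delays_off <- c()
  detected <- rep(FALSE, nrow(out))

  for (mv in effectors) {
    chn <- find_channel(mv)
    rows <- which(out$trial_type == mv)
    if (is.na(chn)) next
    # linear envelope: Gaussian smoothing there is symmetric around the burst
    # edges, so the half-maximum refinement is unbiased
    e <- env[, chn]
    # baseline: samples far from this effector's cues
    near <- epoch_envelope(length(e), fs,
                           out$onset_s[rows] - search_pad_s,
                           out$onset_s[rows] + out$duration_s[rows] + 1,
                           ramp_s = 0.01)
    base <- e[near < 0.5]
    thr <- mean(base) + threshold_sd * sd(base)
    if (!any(e > thr)) {
      abort(sprintf("no supra-threshold activity on EMG channel '%s'", chn),
            class = "motormapr_flat_emg")
    }
    for (i in rows) {
      hit <- detect_burst(e, fs, out$onset_s[i] - 0.3,
                          out$onset_s[i] + out$duration_s[i] + search_pad_s,
                          thr, min_duration_s)
      if (is.null(hit)) next
      delays_on <- c(delays_on, hit["onset"] - out$onset_s[i])
      delays_off <- c(delays_off, hit["offset"] - (out$onset_s[i] + out$duration_s[i]))
      out$duration_s[i] <- hit["offset"] - hit["onset"]
      out$onset_s[i] <- hit["onset"]
      detected[i] <- TRUE
    }
  }

  if (!any(detected)) abort("no EMG bursts detected for any effector")
  # fallback: undetected trials (missing channel or missed burst) get the
  # cue epoch shifted by the average detected delay
  if (any(!detected)) {
    mvs <- unique(out$trial_type[!detected])
    inform(sprintf("EMG not detected for %d trial(s) (%s); shifting cue timing by mean EMG delay",
                   sum(!detected), paste(mvs, collapse = ", ")))
    don <- mean(delays_on); doff <- mean(delays_off)
    i <- which(!detected)
    ends <- out$onset_s[i] + out$duration_s[i] + doff
    out$onset_s[i] <- out$onset_s[i] + don
    out$duration_s[i] <- ends - out$onset_s[i]
  }

  # rest epochs: keep the follows tag; start no earlier than the EMG offset
  rest <- events[events$trial_type == "rest", ]
  rest$source <- "emg"
  ends <- rest$onset_s + rest$duration_s
  for (i in seq_len(nrow(rest))) {
    prev <- out[out$onset_s < ends[i], ]
    if (!nrow(prev)) next
    prev_end <- max(prev$onset_s + prev$duration_s)
    if (prev_end > rest$onset_s[i]) {
      rest$onset_s[i] <- prev_end
      rest$duration_s[i] <- ends[i] - prev_end
    }
  }
  rest <- rest[rest$duration_s > 0, ]
  validate_events(dplyr::arrange(dplyr::bind_rows(out, rest), .data$onset_s))
}
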