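#' Construct a multichannel recording
#'
#' A recording couples a samples-by-channels voltage matrix (microvolts) with
#' its sampling rate and a channel table. Depth-electrode (sEEG) contacts are
#' identified by lead, segment and contact index; surface EMG channels carry
#' `kind = "emg"`.
#'
#' @param data numeric matrix, samples in rows, channels in columns. Column
#'   names, if present, must match `channels$name`.
#' @param fs sampling rate in Hz (> 0).
#' @param channels tibble with columns `name`, `kind` (`"seeg"` or `"emg"`),
#'   `lead_id`, `segment_id`, `contact_index`, and optional coordinates
#'   `x`, `y`, `z` (mm).
#' @return an object of class `seeg_recording`.
#' @export
new_recording <- function(data, fs, channels) {
  channels <- as_tibble(channels)
  needed <- c("name", "kind", "lead_id", "segment_id", "contact_index")
  missing_cols <- setdiff(needed, names(channels))
  if (length(missing_cols)) {
    abort(paste0("channel table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (co in c("x", "y", "z")) if (!co %in% names(channels)) channels[[co]] <- NA_real_
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) != nrow(channels)) {
    abort(sprintf("data has %d channels but channel table has %d rows",
                  ncol(data), nrow(channels)),
          class = "motormapr_format_error")
  }
  colnames(data) <- channels$name
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("fs must be a positive scalar")
  if (!all(channels$kind %in% c("seeg", "emg"))) abort("channel kind must be 'seeg' or 'emg'")
  # contact indices strictly increasing within each lead segment
  seeg <- channels[channels$kind == "seeg", ]
  if (nrow(seeg)) {
    bad <- seeg |>
      dplyr::group_by(.data$lead_id, .data$segment_id) |>
      dplyr::summarise(ok = !is.unsorted(.data$contact_index, strictly = TRUE),
                       .groups = "drop")
    if (!all(bad$ok)) abort("contact_index must be strictly increasing within a lead segment")
  }
  structure(list(data = data, fs = fs, channels = channels),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("<%s> %d channels x %d samples @ %g Hz (%.1f s)\n",
              class(x)[1], ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat(sprintf("  seeg: %d, emg: %d\n",
              sum(x$channels$kind == "seeg"), sum(x$channels$kind == "emg")))
  invisible(x)
}

#' @export
dim.seeg_recording <- function(x) dim(x$data)

#' Validate a task event table
#'
#' Events are rows of `onset_s`, `duration_s`, `trial_type` (`hand`, `tongue`,
#' `foot` or `rest`), `source` (`cue` or `emg`) and, for rest rows, `follows` —
#' the movement type of the preceding trial (used to pair each movement with
#' the rest period that followed it). Onsets must be non-decreasing, durations
#' positive, and epochs from the same source must not overlap.
#'
#' @param events data frame of events.
#' @return the validated events as a tibble (invisibly usable in pipes).
#' @export
validate_events <- function(events) {
  events <- as_tibble(events)
  needed <- c("onset_s", "duration_s", "trial_type", "source")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols)) {
    abort(paste0("events lack column(s): ", paste(missing_cols, collapse = ", ")),
          class = "motormapr_format_error")
  }
  if (!"follows" %in% names(events)) events$follows <- NA_character_
  if (nrow(events) == 0) return(events)
  if (any(events$duration_s <= 0)) abort("durations must be > 0", class = "motormapr_format_error")
  if (is.unsorted(events$onset_s)) abort("onsets must be non-decreasing", class = "motormapr_format_error")
  ok_types <- c(MOVEMENTS, "rest")
  if (!all(events$trial_type %in% ok_types)) {
    abort("trial_type must be one of hand/tongue/foot/rest", class = "motormapr_format_error")
  }
  if (!all(events$source %in% c("cue", "emg"))) {
    abort("source must be 'cue' or 'emg'", class = "motormapr_format_error")
  }
  tol <- 1e-9
  for (src in unique(events$source)) {
    e <- events[events$source == src, ]
    if (nrow(e) > 1) {
      ends <- e$onset_s + e$duration_s
      if (any(e$onset_s[-1] < ends[-nrow(e)] - tol)) {
        abort(sprintf("overlapping epochs within source '%s'", src),
              class = "motormapr_format_error")
      }
    }
  }
  events
}
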