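#' Write a session to disk
#'
#' A session directory holds the voltage timeseries as an Arrow/Feather table
#' (`timeseries.feather`, one float64 column per channel — bit-exact round
#' trip), BIDS-style `events.tsv` and `channels.tsv` sidecars, and `meta.json`
#' with the sampling rate.
#'
#' @param recording a [new_recording()] object.
#' @param events task event table (see [validate_events()]).
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(recording, events, path) {
  stopifnot(inherits(recording, "seeg_recording"))
  events <- validate_events(events)
  if (anyNA(recording$data)) {
    abort("recording data contain NaN/NA; refusing to write", class = "motormapr_format_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create session directory '%s'", path))
  arrow::write_feather(as.data.frame(recording$data),
                       file.path(path, "timeseries.feather"))
  readr::write_tsv(events, file.path(path, "events.tsv"))
  readr::write_tsv(recording$channels, file.path(path, "channels.tsv"))
  jsonlite::write_json(list(fs = recording$fs), file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from disk
#'
#' Inverse of [write_session()]; numeric payloads round-trip bit-exactly.
#' Invariants (channel-count match, event overlap, contact ordering) are
#' re-checked on load.
#'
#' @param path session directory.
#' @return list with elements `recording` and `events`.
#' @export
read_session <- function(path) {
  for (f in c("timeseries.feather", "events.tsv", "channels.tsv", "meta.json")) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("session is missing '%s'", f), class = "motormapr_format_error")
    }
  }
  dat <- as.matrix(as.data.frame(arrow::read_feather(file.path(path, "timeseries.feather"))))
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  channels <- readr::read_tsv(file.path(path, "channels.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  events <- readr::read_tsv(file.path(path, "events.tsv"),
                            show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              onset_s = "d", duration_s = "d",
                              trial_type = "c", source = "c", follows = "c"))
  events <- validate_events(events)
  rec <- new_recording(dat, fs = as.numeric(meta$fs), channels = channels)
  list(recording = rec, events = events)
}

#' Summarise and validate a stored session
#'
#' Loads a session, re-checks all invariants and returns a one-row summary
#' tibble (channel counts, duration, trial counts).
#'
#' @param path session directory.
#' @return tibble with one row.
#' @export
validate_session <- function(path) {
  s <- read_session(path)
  tibble(
    path = path,
    fs = s$recording$fs,
    n_seeg = sum(s$recording$channels$kind == "seeg"),
    n_emg = sum(s$recording$channels$kind == "emg"),
    duration_s = nrow(s$recording$data) / s$recording$fs,
    n_move_epochs = sum(s$events$trial_type != "rest"),
    n_rest_epochs = sum(s$events$trial_type == "rest")
  )
}
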