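## Somatotopic delineation and shared-representation scoring.

# fixed complex basis, 120 degrees apart
SOMATOTOPY_BASIS <- c(hand = complex(argument = pi / 6),
                      tongue = complex(argument = 5 * pi / 6),
                      foot = complex(argument = 3 * pi / 2))

#' Somatotopic tuning vector per channel
#'
#' Multiplies each channel's per-movement r-squared (negative values set to
#' zero first) by unit vectors `exp(i*pi/6)` (hand), `exp(i*5*pi/6)` (tongue)
#' and `exp(i*3*pi/2)` (foot) and sums. The magnitude of the result measures
#' somatotopic selectivity; the phase angle points to the preferred movement
#' (a channel equally active for all three movements cancels to zero).
#'
#' @param stats `channel_stats` tibble from [movement_stats()].
#' @return tibble: `channel`, `tuning` (complex), `magnitude`,
#'   `angle` (radians in \[0, 2*pi)).
#' @export
somatotopy_vector <- function(stats) {
  wide <- stats_to_wide(stats, value = "r2")
  r2 <- pmax(as.matrix(wide[, MOVEMENTS]), 0)  # clip rare negative r2 at 0
  tuning <- as.vector(r2 %*% SOMATOTOPY_BASIS[MOVEMENTS])
  tibble(channel = wide$channel,
         tuning = tuning,
         magnitude = Mod(tuning),
         angle = Arg(tuning) %% (2 * pi))
}

#' Shared-representation overlap per channel
#'
#' Geometric mean of the three movements' significant r-squared values,
#' `(r2_H * r2_T * r2_F)^(1/3)`: a movement whose t-test p-value is at or
#' above `alpha` (or whose r2 is not positive) contributes 0, annihilating the
#' product — overlap is high only where all three movements activate the
#' channel.
#'
#' @param stats `channel_stats` tibble.
#' @param alpha significance cutoff for inclusion (default 0.05).
#' @return tibble: `channel`, `overlap`.
#' @export
shared_overlap <- function(stats, alpha = 0.05) {
  wide_r2 <- stats_to_wide(stats, "r2")
  wide_p <- stats_to_wide(stats, "p")
  r2 <- pmax(as.matrix(wide_r2[, MOVEMENTS]), 0)
  p <- as.matrix(wide_p[, MOVEMENTS])
  r2[!is.finite(p) | p >= alpha] <- 0
  tibble(channel = wide_r2$channel,
         overlap = apply(r2, 1, function(v) prod(v)^(1 / 3)))
}

#' Display-threshold masks for somatotopy and overlap maps
#'
#' Combines the tuning vector and overlap score into one map table and adds
#' the display masks: channels exceeding 50% of the within-session maximum
#' magnitude (somatotopy display), 50% of the maximum overlap (shared
#' representation display), and the per-movement single-modality cutoff at 1%
#' of that movement's maximum r-squared. An all-zero map yields empty masks.
#'
#' @param stats `channel_stats` tibble.
#' @param alpha significance cutoff passed to [shared_overlap()].
#' @return tibble with per-channel `angle`, `magnitude`, `overlap`,
#'   `magnitude_mask`, `overlap_mask` and `sig_hand`/`sig_tongue`/`sig_foot`.
#' @export
threshold_maps <- function(stats, alpha = 0.05) {
  sv <- somatotopy_vector(stats)
  ov <- shared_overlap(stats, alpha)
  wide_r2 <- stats_to_wide(stats, "r2")
  out <- dplyr::left_join(dplyr::select(sv, "channel", "angle", "magnitude"),
                          ov, by = "channel")
  out$magnitude_mask <- out$magnitude > 0.5 * max(out$magnitude)
  out$overlap_mask <- out$overlap > 0.5 * max(out$overlap)
  for (mv in MOVEMENTS) {
    r2 <- pmax(wide_r2[[mv]], 0)
    out[[paste0("sig_", mv)]] <- r2 > 0.01 * max(r2)
  }
  out
}

stats_to_wide <- function(stats, value = "r2") {
  stopifnot(all(c("channel", "movement", value) %in% names(stats)))
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(stats), "channel", "movement", dplyr::all_of(value)),
    names_from = "movement", values_from = dplyr::all_of(value))
  missing_mv <- setdiff(MOVEMENTS, names(wide))
  if (length(missing_mv)) {
    abort(paste0("stats lack movement(s): ", paste(missing_mv, collapse = ", ")))
  }
  incomplete <- !stats::complete.cases(wide[, MOVEMENTS])
  if (any(incomplete)) {
    warn(sprintf("%d channel(s) with missing statistics excluded", sum(incomplete)))
    wide <- wide[!incomplete, ]
  }
  wide
}
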