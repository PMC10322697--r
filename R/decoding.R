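#' Select channel groups for decoding
#'
#' Classifies channels by their per-movement t-test p-values: `"rma"` when all
#' three movements are significant at `p < 0.05` independently;
#' `"somatotopic"` when exactly one movement passes the Bonferroni-corrected
#' `p < 0.05/3` cutoff; channels significant (at the corrected cutoff) for two
#' movements, or for none, are excluded from classification.
#'
#' @param stats `channel_stats` tibble.
#' @param alpha_rma per-movement cutoff for the shared group (default 0.05).
#' @param alpha_somato corrected cutoff for single-movement selectivity
#'   (default 0.05/3).
#' @return tibble: `channel`, `group` in
#'   `rma`/`somatotopic`/`excluded_two`/`excluded_none`.
#' @export
select_decoding_channels <- function(stats, alpha_rma = 0.05,
                                     alpha_somato = 0.05 / 3) {
  wide <- stats_to_wide(stats, "p")
  p <- as.matrix(wide[, MOVEMENTS])
  n_sig <- rowSums(p < alpha_somato)
  group <- dplyr::case_when(
    rowSums(p < alpha_rma) == 3 ~ "rma",
    n_sig == 1 ~ "somatotopic",
    n_sig == 2 ~ "excluded_two",
    TRUE ~ "excluded_none")
  tibble(channel = wide$channel, group = group)
}

# minimal pooled-covariance Gaussian classifier with diagonal shrinkage;
# fallback when lda() rejects singular/constant features
shrinkage_lda <- function(x, y, lambda = 0.1) {
  classes <- sort(unique(y))
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  resid <- x - mu[match(y, classes), , drop = FALSE]
  S <- crossprod(resid) / (nrow(x) - length(classes))
  scale_ <- mean(diag(S))
  if (!is.finite(scale_) || scale_ <= 0) scale_ <- 1  # all-constant features
  S <- (1 - lambda) * S + lambda * scale_ * diag(ncol(x))
  Sinv <- solve(S)
  prior <- as.numeric(table(factor(y, classes))) / length(y)
  list(classes = classes, mu = mu, Sinv = Sinv, prior = prior)
}

predict_shrinkage_lda <- function(fit, x) {
  scores <- sapply(seq_along(fit$classes), function(i) {
    m <- fit$mu[i, ]
    as.numeric(x %*% (fit$Sinv %*% m)) - 0.5 * sum(m * (fit$Sinv %*% m)) +
      log(fit$prior[i])
  })
  scores <- matrix(scores, nrow = nrow(x))
  fit$classes[max.col(scores)]
}

#' Decode movement class from trial band power
#'
#' Four-class (hand/tongue/foot/rest) linear discriminant analysis with
#' stratified threefold cross-validation, run separately for each channel
#' group. Features are each trial's normalized broadband power on the group's
#' channels. All movement and rest trials enter training; accuracy is reported
#' both over all test trials and over movement test trials only — the latter
#' scored from the same fitted four-class models, never retrained on three
#' classes.
#'
#' @param powers tibble from [band_power()].
#' @param groups tibble from [select_decoding_channels()]; only `rma` and
#'   `somatotopic` groups are decoded.
#' @param folds number of CV folds (default 3).
#' @param seed seed for the stratified fold assignment.
#' @return `decoding_result` tibble: one row per group with both accuracies;
#'   confusion matrices and fold assignments in attributes.
#' @export
decode_movements <- function(powers, groups, folds = 3, seed = 1L) {
  feat <- tidyr::pivot_wider(
    dplyr::select(powers, "channel", "epoch", "trial_type", "power"),
    names_from = "channel", values_from = "power")
  feat$class <- ifelse(feat$trial_type == "rest", "rest", feat$trial_type)
  classes <- factor(feat$class, levels = c(MOVEMENTS, "rest"))
  # stratified, seed-deterministic folds
  fold <- integer(nrow(feat))
  withr::with_seed(seed, {
    for (cl in levels(classes)) {
      idx <- which(classes == cl)
      if (length(idx) < folds) {
        abort(sprintf("class '%s' has fewer trials (%d) than folds (%d)",
                      cl, length(idx), folds))
      }
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })

  results <- list()
  confusions <- list()
  for (grp in intersect(c("rma", "somatotopic"), unique(groups$group))) {
    chs <- groups$channel[groups$group == grp]
    chs <- intersect(chs, names(feat))
    if (!length(chs)) next
    X <- as.matrix(feat[, chs, drop = FALSE])
    pred <- character(nrow(X))
    used_shrinkage <- FALSE
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- tryCatch(
        MASS::lda(X[tr, , drop = FALSE], grouping = classes[tr]),
        error = function(e) NULL)
      if (is.null(fit)) {
        used_shrinkage <- TRUE
        sfit <- shrinkage_lda(X[tr, , drop = FALSE], as.character(classes[tr]))
        pred[te] <- predict_shrinkage_lda(sfit, X[te, , drop = FALSE])
      } else {
        pred[te] <- as.character(predict(fit, X[te, , drop = FALSE])$class)
      }
    }
    if (used_shrinkage) inform(sprintf("group '%s': singular pooled covariance, used shrinkage LDA", grp))
    is_move <- classes != "rest"
    results[[length(results) + 1L]] <- tibble(
      group = grp,
      n_channels = length(chs),
      n_trials = nrow(X),
      accuracy_all = mean(pred == as.character(classes)),
      accuracy_movement = mean(pred[is_move] == as.character(classes)[is_move]),
      used_shrinkage = used_shrinkage)
    confusions[[grp]] <- table(truth = classes, predicted = factor(pred, levels(classes)))
  }
  if (!length(results)) {
    inform("no decodable channel groups; returning empty result")
    out <- tibble(group = character(), n_channels = integer(), n_trials = integer(),
                  accuracy_all = numeric(), accuracy_movement = numeric(),
                  used_shrinkage = logical())
  } else {
    out <- dplyr::bind_rows(results)
  }
  attr(out, "confusion") <- confusions
  attr(out, "fold") <- fold
  class(out) <- c("decoding_result", class(out))
  out
}
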