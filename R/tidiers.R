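#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy cluster_selection
#' @export
tidy.cluster_selection <- function(x, ...) {
  x$labels
}

#' @method glance cluster_selection
#' @export
glance.cluster_selection <- function(x, ...) {
  tibble(k_selected = x$k_selected,
         alpha = x$alpha,
         restarts = x$restarts,
         sum_dist = x$penalty_curve$sum_dist[x$k_selected],
         tot_withinss = x$penalty_curve$tot_withinss[x$k_selected],
         penalty = x$penalty_curve$penalty[x$k_selected],
         vote_share = x$penalty_curve$votes[x$k_selected] / x$restarts)
}

#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  conf <- attr(x, "confusion")
  purrr::map_dfr(names(conf), function(g) {
    d <- as.data.frame(conf[[g]])
    tibble(group = g, truth = as.character(d$truth),
           predicted = as.character(d$predicted), n = d$Freq)
  })
}

#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("group", "n_channels", "n_trials",
                                 "accuracy_all", "accuracy_movement")])
}

#' @method tidy trial_psd
#' @export
tidy.trial_psd <- function(x, ...) {
  ep <- x$epochs
  purrr::map_dfr(seq_along(x$channels), function(i) {
    tibble(channel = x$channels[i],
           epoch = rep(ep$epoch, each = length(x$freq)),
           trial_type = rep(ep$trial_type, each = length(x$freq)),
           freq = rep(x$freq, nrow(ep)),
           power = as.numeric(t(x$psd[i, , ])))
  })
}
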