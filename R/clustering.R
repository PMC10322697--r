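#' Build the 3D r-squared feature space
#'
#' One point per channel with the signed r-squared values for foot, hand and
#' tongue on the x, y and z axes (in that fixed order). Unlike the somatotopy
#' map, negative values are kept signed here. Channels missing a movement are
#' excluded with a warning.
#'
#' @param stats `channel_stats` tibble.
#' @return tibble: `channel`, `foot`, `hand`, `tongue`.
#' @export
build_feature_space <- function(stats) {
  wide <- stats_to_wide(stats, "r2")
  dplyr::select(wide, "channel", "foot", "hand", "tongue")
}

# k-means++ seeding; returns row indices of the chosen centers
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        idx[j] <- sample.int(n, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, rowSums((X - matrix(X[idx[j], ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  idx
}

fit_kmeans_once <- function(X, k) {
  if (k == 1) {
    ctr <- matrix(colMeans(X), 1)
    d2 <- rowSums(sweep(X, 2, ctr)^2)
    return(list(sum_dist = sum(sqrt(d2)), tot_withinss = sum(d2),
                cluster = rep(1L, nrow(X)), centers = ctr))
  }
  centers <- X[kmeanspp_centers(X, k), , drop = FALSE]
  if (nrow(unique(centers)) < k) return(NULL)  # degenerate draw
  km <- suppressWarnings(
    kmeans(X, centers = centers, iter.max = 300, algorithm = "Lloyd"))
  d2 <- rowSums((X - km$centers[km$cluster, , drop = FALSE])^2)
  list(sum_dist = sum(sqrt(d2)), tot_withinss = km$tot.withinss,
       cluster = km$cluster, centers = km$centers)
}

#' Penalty-based selection of the number of k-means clusters
#'
#' Repeats k-means (Lloyd, k-means++ seeding) over `k = 1..k_max` for
#' `restarts` random restarts. The clustering error is the summed Euclidean
#' distance of every channel to its assigned cluster center; within each
#' restart the chosen k minimizes the penalty `k^alpha * error`. The selected
#' k is the mode of those per-restart choices (ties broken toward smaller k),
#' and the final labels come from the restart with the minimum error at the
#' selected k. `alpha = 2` strongly favors few clusters and `alpha = 1/2`
#' trades cluster count against error with an interior optimum; unsquared
#' distances matter — a squared-error version decays faster than any
#' `k^(1/2)` penalty grows in 3D, so its minimum degenerates to `k_max`.
#'
#' @param features tibble from [build_feature_space()] (or any tibble with a
#'   `channel` column plus numeric feature columns).
#' @param alpha penalty exponent (default 1/2).
#' @param k_max largest k tried (default 20).
#' @param restarts random restarts (default 1000).
#' @param seed integer seed for reproducibility.
#' @return object of class `cluster_selection`: selected k, per-channel
#'   labels, centers, the vote histogram and the best-of-restarts penalty
#'   curve.
#' @export
select_cluster_count <- function(features, alpha = 0.5, k_max = 20,
                                 restarts = 1000, seed = 1L) {
  X <- as.matrix(features[, setdiff(names(features), "channel"), drop = FALSE])
  storage.mode(X) <- "double"
  n_distinct <- nrow(unique(X))
  ks <- seq_len(min(k_max, nrow(X)))
  best_err <- rep(Inf, length(ks))
  best_ss <- rep(Inf, length(ks))
  best_fit <- vector("list", length(ks))
  votes <- integer(length(ks))
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      err <- rep(Inf, length(ks))
      for (k in ks) {
        if (k > n_distinct) break
        fit <- fit_kmeans_once(X, k)
        if (is.null(fit)) next
        err[k] <- fit$sum_dist
        if (fit$sum_dist < best_err[k]) {
          best_err[k] <- fit$sum_dist
          best_ss[k] <- fit$tot_withinss
          best_fit[[k]] <- fit
        }
      }
      pen <- ks^alpha * err
      votes[which.min(pen)] <- votes[which.min(pen)] + 1L  # ties -> smaller k
    }
  })
  k_sel <- which.max(votes)  # modal k; which.max breaks ties toward smaller k
  if (any(diff(best_err[is.finite(best_err)]) > 1e-8)) {
    warn("best-of-restarts error not monotone in k (rare restart shortfall)")
  }
  structure(list(
    k_selected = k_sel,
    labels = tibble(channel = features$channel,
                    cluster = best_fit[[k_sel]]$cluster),
    centers = best_fit[[k_sel]]$centers,
    feature_names = colnames(X),
    penalty_curve = tibble(k = ks, sum_dist = best_err,
                           tot_withinss = best_ss,
                           penalty = ks^alpha * best_err,
                           votes = votes),
    alpha = alpha, restarts = restarts, seed = seed),
    class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> k = %d (modal over %d restarts, alpha = %g)\n",
              x$k_selected, x$restarts, x$alpha))
  invisible(x)
}

#' Name clusters by centroid geometry
#'
#' A centroid near the origin is `"inactive"`; one with all coordinates
#' positive and balanced (smallest at least half the largest) is `"rma"`
#' (shared representation); all-negative balanced centroids — the widespread
#' nonspecific power decrease seen in low-frequency bands — are
#' `"suppressed"`; one dominated by a single axis (largest at least twice the
#' runner-up) is that effector; anything else is `"unlabeled"`.
#'
#' @param selection a [select_cluster_count()] result.
#' @param origin_radius magnitude below which a centroid counts as inactive.
#' @return tibble: `cluster`, `label`, centroid coordinates.
#' @export
label_clusters <- function(selection, origin_radius = 0.15) {
  ctr <- selection$centers
  axes <- selection$feature_names
  labs <- character(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    v <- ctr[i, ]
    a <- sort(abs(v), decreasing = TRUE)
    if (max(abs(v)) < origin_radius) {
      labs[i] <- "inactive"
    } else if (min(v) > 0 && min(v) / max(v) >= 0.5) {
      labs[i] <- "rma"
    } else if (max(v) < 0 && max(v) / min(v) >= 0.5) {
      labs[i] <- "suppressed"
    } else if (a[1] >= 2 * a[2] && v[which.max(abs(v))] > 0) {
      labs[i] <- axes[which.max(abs(v))]
    } else {
      labs[i] <- "unlabeled"
    }
  }
  out <- tibble(cluster = seq_len(nrow(ctr)), label = labs)
  dplyr::bind_cols(out, as_tibble(ctr, .name_repair = ~axes))
}
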