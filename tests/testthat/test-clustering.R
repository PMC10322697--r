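blob <- function(n, center, sd = 0.05, seed_offset = 0) {
  matrix(rnorm(n * 3, sd = sd), n) + matrix(center, n, 3, byrow = TRUE)
}

features_tbl <- function(X) {
  tibble::tibble(channel = paste0("c", seq_len(nrow(X))),
                 foot = X[, 1], hand = X[, 2], tongue = X[, 3])
}

test_that("feature space puts channels on the foot/hand/tongue axes", {
  p <- small_prep()
  f <- build_feature_space(p$st)
  expect_equal(names(f), c("channel", "foot", "hand", "tongue"))
  gt <- p$gt$channels
  hand <- f[f$channel %in% gt$pair[gt$class == "somatotopic_hand"], ]
  expect_true(all(hand$hand > 0.5 & abs(hand$foot) < 0.3 & abs(hand$tongue) < 0.3))
  rma <- f[f$channel %in% gt$pair[gt$class == "rma"], ]
  expect_true(all(rma$foot > 0.5 & rma$hand > 0.5 & rma$tongue > 0.5))
  inact <- f[f$channel %in% gt$pair[gt$class == "inactive"], ]
  expect_true(all(sqrt(inact$foot^2 + inact$hand^2 + inact$tongue^2) < 0.3))
})

test_that("four well-separated blobs select k = 4 at alpha = 1/2", {
  withr::local_seed(31)
  X <- rbind(blob(20, c(0, 0, 0)), blob(20, c(1, 1, 1)),
             blob(20, c(0, 0, 3)), blob(20, c(-2, -2, -2)))
  ks <- sapply(1:5, function(s)
    select_cluster_count(features_tbl(X), alpha = 0.5, restarts = 100,
                         seed = s)$k_selected)
  expect_true(all(ks == 4))
})

test_that("larger penalty exponents select no more clusters", {
  # for a fixed error curve, argmin_k k^alpha * error(k) is non-increasing
  # in alpha: the exponent steers between over- and under-clustering
  withr::local_seed(32)
  X <- rbind(blob(25, c(0, 0, 0), sd = 0.08), blob(15, c(0.9, 0.1, 0), sd = 0.2),
             blob(15, c(0, 0.9, 0.1), sd = 0.2), blob(15, c(0.8, 0.8, 0.8), sd = 0.25))
  f <- features_tbl(X)
  k1 <- select_cluster_count(f, alpha = 1, restarts = 80, seed = 1)$k_selected
  k05 <- select_cluster_count(f, alpha = 0.5, restarts = 80, seed = 1)$k_selected
  k2 <- select_cluster_count(f, alpha = 2, restarts = 80, seed = 1)$k_selected
  expect_gte(k05, k1)
  expect_gte(k1, k2)
  expect_lte(k2, 2)
})

test_that("selection bookkeeping: monotone error, scale covariance, degenerate input", {
  withr::local_seed(33)
  X <- rbind(blob(20, c(0, 0, 0), sd = 0.3), blob(20, c(2, 0, 1), sd = 0.3))
  f <- features_tbl(X)
  sel <- select_cluster_count(f, alpha = 0.5, restarts = 60, seed = 2)
  err <- sel$penalty_curve$sum_dist
  expect_true(all(diff(err[is.finite(err)]) <= 1e-8))
  expect_equal(sum(sel$penalty_curve$votes), 60)
  # multiplying features by a constant cannot change the selected k
  f10 <- f; f10[, 2:4] <- f10[, 2:4] * 10
  sel10 <- select_cluster_count(f10, alpha = 0.5, restarts = 60, seed = 2)
  expect_equal(sel10$k_selected, sel$k_selected)
  # identical points collapse to a single cluster
  same <- features_tbl(matrix(1, 25, 3))
  expect_equal(select_cluster_count(same, restarts = 10, seed = 1)$k_selected, 1)
})

test_that("centroid geometry rules name the clusters", {
  sel <- structure(list(
    centers = rbind(c(0, 0, 0.4), c(0.2, 0.2, 0.2), c(0.01, -0.02, 0.03),
                    c(-0.5, -0.45, -0.5), c(0.6, 0.35, 0.05)),
    feature_names = c("foot", "hand", "tongue")),
    class = "cluster_selection")
  labs <- label_clusters(sel)
  expect_equal(labs$label,
               c("tongue", "rma", "inactive", "suppressed", "unlabeled"))
})

test_that("pooled synthetic sessions cluster into the ground-truth classes", {
  st <- cached("pooled_bb_acc", pooled_stats(1:4))
  sel <- select_cluster_count(build_feature_space(st), alpha = 0.5,
                              restarts = 150, seed = 7)
  expect_equal(sel$k_selected, 5)
  lab <- dplyr::left_join(tidy(sel),
                          label_clusters(sel)[, c("cluster", "label")],
                          by = "cluster")
  truth <- gt_label(st$gt_class[match(lab$channel, st$channel)])
  expect_gte(rand_index(lab$label, truth), 0.9)
  # semantic labels agree with ground truth for nearly all channels
  expect_gt(mean(lab$label == truth), 0.9)
})
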