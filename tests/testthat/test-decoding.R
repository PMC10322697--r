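test_that("channel groups follow the significance rules", {
  p <- matrix(c(0.04, 0.03, 0.01,    # all < 0.05          -> rma
                0.001, 0.5, 0.9,     # one < 0.05/3        -> somatotopic
                0.001, 0.01, 0.9,    # two < 0.05/3        -> excluded
                0.2, 0.3, 0.4),      # none                -> excluded
              ncol = 3, byrow = TRUE)
  g <- select_decoding_channels(make_stats(matrix(0.3, 4, 3), p = p))
  expect_equal(g$group, c("rma", "somatotopic", "excluded_two", "excluded_none"))
})

test_that("folds are stratified and seed-deterministic", {
  p <- small_prep()
  pw <- band_power(p$tp)
  groups <- select_decoding_channels(p$st)
  d1 <- decode_movements(pw, groups, seed = 3)
  d2 <- decode_movements(pw, groups, seed = 3)
  expect_identical(attr(d1, "fold"), attr(d2, "fold"))
  expect_identical(glance(d1), glance(d2))
  # each class is spread over all folds
  classes <- ifelse(p$tp$epochs$trial_type == "rest", "rest", p$tp$epochs$trial_type)
  tab <- table(classes, attr(d1, "fold"))
  expect_true(all(tab > 0))
})

test_that("synthetic sessions decode well and movement-only scores reuse the same models", {
  sess <- cached("decode_sess", {
    synthesize_session(generator_spec(seed = 77, g_bb = 4, gain_sd = 0.4,
                                      plan = small_plan))
  })
  bp <- bipolar_rereference(sess$recording)
  ev <- suppressMessages(emg_epochs(sess$recording, sess$events))
  tp <- trial_psd(bp, ev)
  st <- movement_stats(tp)
  dec <- decode_movements(band_power(tp), select_decoding_channels(st), seed = 5)
  expect_setequal(dec$group, c("rma", "somatotopic"))
  expect_true(all(dec$accuracy_all >= 0.9))
  # movement-only accuracy equals the movement rows of the same confusion
  for (g in dec$group) {
    cm <- attr(dec, "confusion")[[g]]
    mv <- rownames(cm) != "rest"
    expect_equal(dec$accuracy_movement[dec$group == g],
                 sum(diag(cm[mv, mv])) / sum(cm[mv, ]))
  }
  # a single RMA channel still beats chance
  one <- select_decoding_channels(st)
  one <- one[one$group == "rma", ][1, ]
  d1 <- decode_movements(band_power(tp), one, seed = 5)
  expect_gt(d1$accuracy_all, 0.4)
})

test_that("label-shuffled decoding falls to chance", {
  p <- small_prep()
  pw <- band_power(p$tp)
  groups <- select_decoding_channels(p$st)
  # balance the design (20 trials per class incl. rest) so chance is 1/4,
  # then permute the class labels across epochs
  ep <- unique(pw[, c("epoch", "trial_type")])
  accs <- sapply(1:8, function(s) {
    withr::with_seed(100 + s, {
      keep_rest <- sample(ep$epoch[ep$trial_type == "rest"], 20)
      bal <- ep[ep$trial_type != "rest" | ep$epoch %in% keep_rest, ]
      bal$trial_type <- sample(bal$trial_type)
      pw2 <- pw[pw$epoch %in% bal$epoch, ]
      pw2$trial_type <- bal$trial_type[match(pw2$epoch, bal$epoch)]
      dec <- decode_movements(pw2, groups, seed = s)
      mean(dec$accuracy_all)
    })
  })
  # binomial 95% band around 0.25 with 80 balanced trials is (0.155, 0.345);
  # the mean over 8 shuffles sits comfortably inside it
  expect_gt(mean(accs), 0.155)
  expect_lt(mean(accs), 0.345)
})

test_that("degenerate feature sets fall back to shrinkage and empty groups are skipped", {
  p <- small_prep()
  pw <- band_power(p$tp)
  # constant feature: lda() rejects it, shrinkage fallback still decodes
  ch1 <- unique(pw$channel)[1]
  pwc <- pw[pw$channel == ch1, ]
  pwc$power <- 1
  g <- tibble::tibble(channel = ch1, group = "rma")
  expect_message(dec <- decode_movements(pwc, g, seed = 1), "shrinkage")
  expect_true(dec$used_shrinkage)
  # no usable groups: empty result, not an error
  g0 <- tibble::tibble(channel = character(), group = character())
  expect_message(d0 <- decode_movements(pw, g0, seed = 1), "no decodable")
  expect_equal(nrow(d0), 0)
})
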