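noise_recording <- function(secs = 60, seed = 20, fs = 1200, n_emg = 0) {
  withr::with_seed(seed, {
    cn <- motormapr:::colored_noise
    dat <- cbind(20 * cn(secs * fs, fs, 2), 20 * cn(secs * fs, fs, 2))
    if (n_emg) dat <- cbind(dat, rnorm(secs * fs))
    ch <- tibble::tibble(
      name = c("a1", "a2", if (n_emg) "EMG_hand"),
      kind = c("seeg_pair", "seeg_pair", if (n_emg) "emg"),
      lead_id = "L1", segment_id = 1L, contact_index = seq_len(2 + n_emg))
    colnames(dat) <- ch$name
    structure(list(data = dat, fs = fs, channels = ch),
              class = c("bipolar_recording", "seeg_recording"))
  })
}

test_that("broadband timecourse is centered and gain-invariant", {
  rec <- noise_recording()
  tc <- broadband_timecourse(rec)
  # the chain pins the geometric-mean power level at zero: the z-score step
  # guarantees mean(log(1 + output)) ~ 0 (smoothing preserves the mean);
  # the arithmetic mean and median sit near but not exactly at zero because
  # exponentiation is convex and log power is skewed
  expect_lt(abs(mean(log1p(tc$data[, 1]))), 0.01)
  expect_lt(abs(median(tc$data[, 1])), 0.15)
  expect_lt(abs(mean(tc$data[, 1])), 0.5)
  rec10 <- rec; rec10$data <- rec10$data * 10
  tc10 <- broadband_timecourse(rec10)
  expect_equal(tc10$data, tc$data, tolerance = 1e-9)
  # too-low sampling rate is refused
  bad <- rec; bad$fs <- 200
  expect_error(broadband_timecourse(bad), "too low")
})

test_that("broadband timecourse tracks an amplitude-modulated 90 Hz tone", {
  fs <- 1200; secs <- 40
  t_s <- (0:(secs * fs - 1)) / fs
  env <- as.numeric((t_s %% 4) < 2)  # square-wave envelope, 2 s on / 2 s off
  withr::local_seed(21)
  dat <- cbind(sin(2 * pi * 90 * t_s) * (0.2 + env) + 0.01 * rnorm(secs * fs))
  rec <- noise_recording(secs)
  rec$data <- cbind(dat, dat)
  colnames(rec$data) <- rec$channels$name
  tc <- broadband_timecourse(rec)
  mid <- (5 * fs):((secs - 5) * fs)  # skip edge tapers
  expect_gt(stats::cor(tc$data[mid, 1], env[mid]), 0.8)
  # onset rise is no slower than smoothing allows: 10-90% within 4 sd
  on <- tc$data[8 * fs + seq(-0.5 * fs, 0.5 * fs), 1]  # transition at t = 8 s
  rng <- range(on)
  t10 <- min(which(on > rng[1] + 0.1 * diff(rng)))
  t90 <- min(which(on > rng[1] + 0.9 * diff(rng)))
  expect_lt((t90 - t10) / fs, 4 * tc$smooth_sd_s + 0.05)
})

test_that("EMG conditioning suppresses line noise and keeps burst contrast", {
  # notch response oracle: pure 60 Hz attenuated at least 20 dB
  fs <- 1200
  t_s <- (0:(10 * fs - 1)) / fs
  x60 <- sin(2 * pi * 60 * t_s)
  y <- motormapr:::notch_zerophase(x60, fs, 60)
  mid <- (2 * fs):(8 * fs)
  expect_lt(sqrt(mean(y[mid]^2)) / sqrt(mean(x60[mid]^2)), 0.1)

  # burst versus silence contrast on a generated session
  s <- tiny_session()
  env <- condition_emg(s$recording, output = "linear")
  gt <- s$ground_truth$trials
  hand <- gt[gt$movement == "hand", ]
  act <- unlist(lapply(seq_len(nrow(hand)), function(i) {
    env[round(hand$emg_onset_s[i] * 1200):round(hand$emg_offset_s[i] * 1200), "EMG_hand"]
  }))
  rest_idx <- round((hand$emg_offset_s + 0.5) * 1200)
  silent <- unlist(lapply(rest_idx, function(i) env[i:(i + 1200), "EMG_hand"]))
  expect_gt(mean(act) / mean(silent), 5)

  # all-zero channel: constant envelope, no NaN
  rec0 <- s$recording
  rec0$data[, "EMG_foot"] <- 0
  env0 <- condition_emg(rec0)
  expect_true(all(is.finite(env0)))
  expect_equal(sd(env0[, "EMG_foot"]), 0)
})

test_that("event-locked averages start at zero and reduce to single epochs", {
  rec <- noise_recording()
  tc <- broadband_timecourse(rec)
  ev1 <- tibble::tibble(onset_s = 20, duration_s = 3, trial_type = "hand",
                        source = "emg", follows = NA_character_)
  avg1 <- event_locked_average(tc, ev1, channels = "a1")
  expect_equal(avg1$value[1], 0)
  idx <- round(20 * 1200) + round(-0.5 * 1200):round(4 * 1200) + 1
  manual <- tc$data[idx, "a1"]
  expect_equal(avg1$value, manual - manual[1])
  # averaging is linear: two epochs average to the mean of their traces
  ev2 <- tibble::tibble(onset_s = c(20, 40), duration_s = 3, trial_type = "hand",
                        source = "emg", follows = NA_character_)
  avg2 <- event_locked_average(tc, ev2, channels = "a1")
  m1 <- tc$data[round(20 * 1200) + round(-0.5 * 1200):round(4 * 1200) + 1, "a1"]
  m2 <- tc$data[round(40 * 1200) + round(-0.5 * 1200):round(4 * 1200) + 1, "a1"]
  both <- (m1 + m2) / 2
  expect_equal(avg2$value, both - both[1])
  # epochs outside the recording are dropped with a warning
  ev3 <- tibble::tibble(onset_s = c(20, 59.5), duration_s = 3, trial_type = "hand",
                        source = "emg", follows = NA_character_)
  expect_warning(avg3 <- event_locked_average(tc, ev3, channels = "a1"), "dropped")
  expect_equal(unique(avg3$n_epochs), 1)
})

test_that("movement-locked broadband rises during movement on responsive channels", {
  p <- small_prep()
  tc <- cached("small_tc_hand", {
    gt <- p$gt$channels
    hand <- gt$pair[gt$class == "somatotopic_hand"]
    rec <- p$bp
    rec$data <- rec$data[, hand, drop = FALSE]
    rec$channels <- rec$channels[rec$channels$name %in% hand, ]
    broadband_timecourse(rec)
  })
  mv <- p$ev[p$ev$trial_type == "hand", ]
  avg <- event_locked_average(tc, mv)
  during <- avg$value[avg$time_s > 0.5 & avg$time_s < 2.5]
  after <- avg$value[avg$time_s > 3.6]
  expect_gt(mean(during), 0.5)
  expect_lt(mean(after), mean(during) / 2)  # returns toward baseline
})

test_that("latency is exact on shifted copies and flags boundary peaks", {
  withr::local_seed(22)
  fs <- 1200
  x <- motormapr:::gaussian_smooth(rnorm(40 * fs), fs, 0.02)
  for (k in c(-1800, -120, 0, 120, 600)) {
    b <- if (k >= 0) c(rep(0, k), x[1:(40 * fs - k)]) else c(x[(1 - k):(40 * fs)], rep(0, -k))
    tc <- structure(list(data = cbind(ch = x), fs = fs, kind = "broadband"),
                    class = "timecourse")
    lat <- estimate_latency(tc, cbind(EMG_hand = b), max_lag_s = 2, edge_trim_s = 2.5)
    expect_equal(lat$lag_ms, k * 1000 / fs)
    expect_false(lat$at_boundary)
  }
  # a shift just beyond the window pins the peak to the boundary and is flagged
  k <- 2450
  b <- c(rep(0, k), x[1:(40 * fs - k)])
  tc <- structure(list(data = cbind(ch = x), fs = fs, kind = "broadband"),
                  class = "timecourse")
  lat <- estimate_latency(tc, cbind(EMG_hand = b), max_lag_s = 2, edge_trim_s = 2.5)
  expect_true(lat$at_boundary)
})

test_that("generator lead time is recovered from one session", {
  spec <- generator_spec(seed = 30, plan = c(somatotopic_hand = 2, somatotopic_tongue = 0,
                                             somatotopic_foot = 0, rma = 1, inactive = 0))
  sess <- synthesize_session(spec)
  bp <- bipolar_rereference(sess$recording)
  tc <- broadband_timecourse(bp)
  env <- condition_emg(sess$recording, output = "linear")
  lat <- estimate_latency(tc, env)
  gtc <- sess$ground_truth$channels
  own <- dplyr::bind_rows(
    lat[lat$channel %in% gtc$pair[gtc$class == "somatotopic_hand"] & lat$effector == "hand", ],
    lat[lat$channel %in% gtc$pair[gtc$class == "rma"], ])
  expect_lt(abs(median(own$lag_ms) - 100), 40)
  expect_true(all(!own$at_boundary))
})
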