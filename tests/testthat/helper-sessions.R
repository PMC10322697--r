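# Sessions are expensive to synthesize; share them across test files.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tiny_plan <- c(somatotopic_hand = 1, somatotopic_tongue = 1,
               somatotopic_foot = 1, rma = 1, inactive = 2)
small_plan <- c(somatotopic_hand = 3, somatotopic_tongue = 3,
                somatotopic_foot = 3, rma = 3, inactive = 6)

tiny_session <- function() cached("tiny", {
  synthesize_session(generator_spec(seed = 11, plan = tiny_plan))
})

small_session <- function() cached("small", {
  synthesize_session(generator_spec(seed = 42, plan = small_plan))
})

# preprocessed small session: bipolar recording, EMG epochs, trial PSDs, stats
small_prep <- function() cached("small_prep", {
  s <- small_session()
  bp <- bipolar_rereference(s$recording)
  ev <- suppressMessages(emg_epochs(s$recording, s$events))
  tp <- trial_psd(bp, ev)
  st <- movement_stats(tp)
  list(bp = bp, ev = ev, tp = tp, st = st, gt = s$ground_truth)
})

# channel_stats tibble built by hand from r2/p triplets
make_stats <- function(r2, p = NULL) {
  n <- nrow(r2)
  if (is.null(p)) p <- matrix(1e-6, n, 3)
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(channel = paste0("ch", i),
                   movement = c("hand", "tongue", "foot"),
                   r2 = as.numeric(r2[i, ]), p = as.numeric(p[i, ]),
                   n_move = 20L, n_rest = 20L,
                   mean_move = NA_real_, mean_rest = NA_real_)
  })
}

# plain Rand index between two labelings
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  ct <- table(a, b)
  ss <- sum(choose(ct, 2))
  sa <- sum(choose(rowSums(ct), 2))
  sb <- sum(choose(colSums(ct), 2))
  np <- choose(n, 2)
  (np + 2 * ss - sa - sb) / np
}

# map ground-truth generator classes onto cluster label vocabulary
gt_label <- function(class) {
  c(somatotopic_hand = "hand", somatotopic_tongue = "tongue",
    somatotopic_foot = "foot", rma = "rma", inactive = "inactive")[class]
}

# pooled channel stats over several seeded default (or beta) sessions;
# mirrors pooling sessions the way multi-subject cluster analyses pool
# channels
pooled_stats <- function(seeds, preset = "default", band = c(65, 115)) {
  purrr::map_dfr(seeds, function(s) {
    sess <- synthesize_session(generator_spec(seed = s, preset = preset))
    bp <- bipolar_rereference(sess$recording)
    ev <- suppressMessages(emg_epochs(sess$recording, sess$events))
    st <- movement_stats(trial_psd(bp, ev), band = band)
    st$channel <- paste0("s", s, "_", st$channel)
    st$gt_class <- sess$ground_truth$channels$class[
      match(sub("^s[0-9]+_", "", st$channel), sess$ground_truth$channels$pair)]
    rm(sess, bp); gc(verbose = FALSE)
    st
  })
}
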