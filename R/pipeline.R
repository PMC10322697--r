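#' Pipeline configuration
#'
#' Bundles every tunable the end-to-end run needs: the generator settings (or
#' a session path to load instead), the analysis band, the clustering penalty
#' exponent and restart count, and the decoding folds.
#'
#' @param seed master seed: drives generation, clustering restarts and fold
#'   assignment.
#' @param generator named list of [generator_spec()] overrides.
#' @param session_path optional path of a stored session to load instead of
#'   simulating.
#' @param band analysis band, Hz.
#' @param alpha clustering penalty exponent.
#' @param restarts clustering restarts.
#' @param k_max maximum cluster count tried.
#' @param folds decoding CV folds.
#' @param out_dir optional output directory for TSV artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, generator = list(), session_path = NULL,
                            band = c(65, 115), alpha = 0.5, restarts = 1000,
                            k_max = 20, folds = 3, out_dir = NULL) {
  structure(list(seed = as.integer(seed), generator = generator,
                 session_path = session_path, band = band, alpha = alpha,
                 restarts = restarts, k_max = k_max, folds = folds,
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(manifest, name, f) {
  t0 <- Sys.time()
  res <- f()
  manifest$stages[[name]] <- list(
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(manifest = manifest, value = res)
}

#' Run the full mapping pipeline
#'
#' Simulate (or load) a session, bipolar-rereference, re-time epochs to EMG,
#' compute trial PSDs and movement statistics, build somatotopy and overlap
#' maps, cluster the r-squared feature space, and decode movements — returning
#' a manifest of all stage outputs, per-stage timings and drop counts. With
#' `out_dir` set, writes `stats.tsv`, `map.tsv`, `clusters.tsv`,
#' `penalty_curve.tsv` and `decoding.tsv`; identical config + seed reproduces
#' them bit-exactly.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_manifest` with the config snapshot, results
#'   and timings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- list(config = config, stages = list(), outputs = list())

  t_all <- Sys.time()
  if (!is.null(config$session_path)) {
    s <- stage(m, "load", function() read_session(config$session_path))
    m <- s$manifest
    session <- s$value
    ground_truth <- NULL
  } else {
    spec <- do.call(generator_spec, c(list(seed = config$seed), config$generator))
    s <- stage(m, "simulate", function() synthesize_session(spec))
    m <- s$manifest
    session <- s$value
    ground_truth <- session$ground_truth
  }

  s <- stage(m, "preprocess", function() bipolar_rereference(session$recording))
  m <- s$manifest; bp <- s$value
  s <- stage(m, "emg_epochs", function() emg_epochs(session$recording, session$events))
  m <- s$manifest; ev <- s$value
  s <- stage(m, "trial_psd", function() trial_psd(bp, ev))
  m <- s$manifest; tp <- s$value
  s <- stage(m, "stats", function() movement_stats(tp, band = config$band))
  m <- s$manifest; st <- s$value
  s <- stage(m, "map", function() threshold_maps(st))
  m <- s$manifest; map <- s$value
  s <- stage(m, "cluster", function() {
    sel <- select_cluster_count(build_feature_space(st), alpha = config$alpha,
                                k_max = config$k_max, restarts = config$restarts,
                                seed = config$seed)
    list(selection = sel, labels = label_clusters(sel))
  })
  m <- s$manifest; cl <- s$value
  s <- stage(m, "decode", function() {
    decode_movements(band_power(tp, config$band),
                     select_decoding_channels(st),
                     folds = config$folds, seed = config$seed)
  })
  m <- s$manifest; dec <- s$value

  m$counts <- list(
    channels_in = ncol(session$recording$data),
    pairs = sum(bp$channels$kind == "seeg_pair"),
    epochs_used = nrow(tp$epochs),
    epochs_dropped = nrow(ev) - nrow(tp$epochs))

  m$results <- list(stats = st, map = map,
                    cluster_selection = cl$selection,
                    cluster_labels = cl$labels,
                    decoding = dec,
                    ground_truth = ground_truth)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      p <- file.path(config$out_dir, name)
      readr::write_tsv(x, p)
      m$outputs[[name]] <<- p
    }
    wr(st, "stats.tsv")
    wr(map, "map.tsv")
    wr(dplyr::left_join(generics::tidy(cl$selection),
                        cl$labels[, c("cluster", "label")], by = "cluster"),
       "clusters.tsv")
    wr(cl$selection$penalty_curve, "penalty_curve.tsv")
    wr(as_tibble(dec), "decoding.tsv")
  }
  m$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  class(m) <- "run_manifest"
  m
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  seed %d, band %g-%g Hz, alpha %g, %d restarts\n",
              x$config$seed, x$config$band[1], x$config$band[2],
              x$config$alpha, x$config$restarts))
  cat(sprintf("  channels in: %d, pairs: %d, epochs used: %d (dropped %d)\n",
              x$counts$channels_in, x$counts$pairs,
              x$counts$epochs_used, x$counts$epochs_dropped))
  cat(sprintf("  clusters: k = %d; decoding groups: %s\n",
              x$results$cluster_selection$k_selected,
              paste(x$results$decoding$group, collapse = ", ")))
  for (s in names(x$stages)) {
    cat(sprintf("  %-12s %6.1f s\n", s, x$stages[[s]]$seconds))
  }
  invisible(x)
}
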