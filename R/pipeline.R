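#' End-to-end run configuration
#'
#' Bundles every tunable of an analysis run. `mode` selects between the
#' full method (`"iqsa"`: superposed windows + boosted ensemble) and the
#' two reconstructed single-tree baselines: `"qsa_nowindow"` forces
#' non-overlapping windows (`t_disp = ns`) and one tree;
#' `"qsa_window"` keeps the configured displacement but still uses a
#' single unboosted tree.
#'
#' @param channels four channel names, scalar component first (default
#'   `c("F3", "F4", "FC5", "FC6")`, the frontal/motor quadruple).
#' @param window a [window_config()].
#' @param n_trees trees in the ensemble (default 10; forced to 1 in the
#'   baseline modes).
#' @param n_repeats independent split/train/test repetitions to average
#'   over (default 20).
#' @param train_frac,fit_frac split fractions (defaults 0.7 and 0.8).
#' @param seed integer base seed; repeat r uses `seed + r - 1`.
#' @param mode `"iqsa"`, `"qsa_nowindow"` or `"qsa_window"`.
#' @param control a [tree_control()].
#' @return a list of class `iqsa_run_config`.
#' @export
run_config <- function(channels = c("F3", "F4", "FC5", "FC6"),
                       window = window_config(), n_trees = 10L,
                       n_repeats = 20L, train_frac = 0.7, fit_frac = 0.8,
                       seed = 1L,
                       mode = c("iqsa", "qsa_nowindow", "qsa_window"),
                       control = tree_control()) {
  mode <- match.arg(mode)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  structure(
    list(channels = channels, window = window, n_trees = as.integer(n_trees),
         n_repeats = as.integer(n_repeats), train_frac = train_frac,
         fit_frac = fit_frac, seed = as.integer(seed), mode = mode,
         control = control),
    class = "iqsa_run_config"
  )
}

resolve_mode <- function(cfg) {
  w <- cfg$window
  if (cfg$mode == "qsa_nowindow") {
    w <- window_config(ns = w$ns, t_disp = w$ns, dt = w$dt,
                       sampling_rate = w$sampling_rate)
  }
  n_trees <- if (cfg$mode == "iqsa") cfg$n_trees else 1L
  list(window = w, n_trees = n_trees)
}

#' Run the full pipeline on a labelled recording
#'
#' Extract window features, then `n_repeats` times: draw a balanced
#' stratified split, train the (boosted or baseline) classifier, predict
#' the held-out test rows and evaluate. Fully deterministic under
#' `cfg$seed`.
#'
#' @param recording a labelled [eeg_recording()].
#' @param cfg a [run_config()].
#' @return an object of class `iqsa_run`: per-repeat `reports`, the
#'   vector `rt` of test recognition rates, `mean_rt` / `min_rt` /
#'   `max_rt`, window count and the resolved configuration.
#' @export
run_iqsa <- function(recording, cfg = run_config()) {
  stopifnot(inherits(cfg, "iqsa_run_config"))
  res <- resolve_mode(cfg)
  features <- build_feature_matrix(recording, res$window,
                                   channels = cfg$channels)
  run_on_features(features, cfg, res)
}

run_on_features <- function(features, cfg, res = resolve_mode(cfg)) {
  reports <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    seed_r <- cfg$seed + r - 1L
    split <- make_split(features, seed = seed_r,
                        train_frac = cfg$train_frac, fit_frac = cfg$fit_frac)
    model <- train_ensemble(features[split$fit, , drop = FALSE],
                            features[split$val, , drop = FALSE],
                            n_trees = res$n_trees, seed = seed_r,
                            control = cfg$control)
    pred <- predict(model, features[split$test, , drop = FALSE])
    reports[[r]] <- evaluate_predictions(features$label[split$test],
                                         pred$class)
  }
  rt <- vapply(reports, `[[`, numeric(1), "rt")
  structure(
    list(reports = reports, rt = rt, mean_rt = mean(rt), min_rt = min(rt),
         max_rt = max(rt), n_windows = nrow(features), mode = cfg$mode,
         config = cfg),
    class = "iqsa_run"
  )
}

#' @export
print.iqsa_run <- function(x, ...) {
  cat(sprintf(
    "<iqsa_run> mode = %s, %d windows, %d repeats\nRT mean %.4f  min %.4f  max %.4f\n",
    x$mode, x$n_windows, length(x$rt), x$mean_rt, x$min_rt, x$max_rt))
  invisible(x)
}

#' Mean accuracy across window sizes
#'
#' Re-runs [run_iqsa()] for each window length, keeping the configured
#' displacement (capped at the window length), and tabulates mean, min
#' and max test recognition rate per size.
#'
#' @param recording a labelled [eeg_recording()].
#' @param cfg a [run_config()].
#' @param sizes window lengths in samples (default
#'   `c(384, 320, 256, 192, 128, 64)`, i.e. 3 s down to 0.5 s at
#'   128 Hz).
#' @return data frame with columns
#'   `ns, seconds, n_windows, mean_rt, min_rt, max_rt`.
#' @export
sweep_windows <- function(recording, cfg = run_config(),
                          sizes = c(384L, 320L, 256L, 192L, 128L, 64L)) {
  if (any(sizes <= cfg$window$dt)) {
    stop("every window size must exceed dt = ", cfg$window$dt)
  }
  rows <- lapply(sizes, function(ns) {
    w <- cfg$window
    cfg_s <- cfg
    cfg_s$window <- window_config(ns = ns, t_disp = min(w$t_disp, ns),
                                  dt = w$dt, sampling_rate = w$sampling_rate)
    run <- run_iqsa(recording, cfg_s)
    data.frame(ns = ns, seconds = ns / w$sampling_rate,
               n_windows = run$n_windows, mean_rt = run$mean_rt,
               min_rt = run$min_rt, max_rt = run$max_rt)
  })
  do.call(rbind, rows)
}

#' Classify a stream of EEG chunks
#'
#' Emulates online use by consuming chunks of arbitrary length: samples
#' are buffered and one class event is emitted for every complete
#' `ns`-sample window displaced by `t_disp`, in arrival order. A
#' trailing partial window at stream end is discarded. Replaying a
#' batch recording chunk by chunk yields exactly the predictions of the
#' batch path.
#'
#' @param model a trained `iqsa_ensemble`.
#' @param chunks list of numeric matrices (samples x named channels).
#' @param cfg a [window_config()].
#' @param channels four channel names, scalar first.
#' @return data frame with columns `start` (0-based window start) and
#'   `class`.
#' @export
stream_classify <- function(model, chunks, cfg = window_config(),
                            channels = c("F3", "F4", "FC5", "FC6")) {
  stopifnot(inherits(model, "iqsa_ensemble"),
            inherits(cfg, "iqsa_window_config"))
  buffer <- NULL
  events <- list()
  next_start <- 0L
  for (chunk in chunks) {
    chunk <- as.matrix(chunk)
    missing_ch <- setdiff(channels, colnames(chunk))
    if (length(missing_ch)) {
      stop("chunk lacks channel(s): ", paste(missing_ch, collapse = ", "))
    }
    buffer <- rbind(buffer, chunk[, channels, drop = FALSE])
    while (nrow(buffer) >= next_start + cfg$ns) {
      idx <- next_start + seq_len(cfg$ns)
      feat <- as.data.frame(t(window_features(
        window_modulus(buffer[idx, , drop = FALSE], cfg$dt))))
      pred <- predict(model, feat)
      events[[length(events) + 1L]] <-
        data.frame(start = next_start, class = pred$class)
      next_start <- next_start + cfg$t_disp
    }
  }
  if (!length(events)) {
    return(data.frame(start = integer(0), class = integer(0)))
  }
  do.call(rbind, events)
}
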