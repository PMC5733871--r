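#' Cue-paradigm configuration for the synthetic session generator
#'
#' One run alternates a fixation cross (rest, class 0) with a
#' left/right arrow cue (motor imagery, classes 1/2), starting and
#' ending with a cross: by default 33 crosses of 3 s and 32 arrows of
#' 5 s at 128 Hz, i.e. 259 s of cued time per run, 3 runs per session.
#' Arrow directions are balanced (half left, half right per run) and
#' shuffled under the session seed.
#'
#' @param sampling_rate Hz (default 128).
#' @param cross_s,arrow_s cue durations in seconds (defaults 3 and 5).
#' @param arrows_per_run,crosses_per_run cue counts per run (defaults
#'   32 and 33).
#' @param runs number of runs per session (default 3).
#' @param channels channel names (default: the 14-electrode 10-20
#'   consumer-headset montage).
#' @return a list of class `iqsa_paradigm`.
#' @export
paradigm_config <- function(sampling_rate = 128, cross_s = 3, arrow_s = 5,
                            arrows_per_run = 32L, crosses_per_run = 33L,
                            runs = 3L,
                            channels = c("AF3", "F7", "F3", "FC5", "T7",
                                         "P7", "O1", "O2", "P8", "T8",
                                         "FC6", "F4", "F8", "AF4")) {
  stopifnot(sampling_rate > 0, cross_s > 0, arrow_s > 0,
            arrows_per_run >= 1, crosses_per_run >= 1, runs >= 1)
  if (!length(channels)) stop("at least one channel required")
  structure(
    list(sampling_rate = sampling_rate, cross_s = cross_s,
         arrow_s = arrow_s, arrows_per_run = as.integer(arrows_per_run),
         crosses_per_run = as.integer(crosses_per_run),
         runs = as.integer(runs), channels = channels),
    class = "iqsa_paradigm"
  )
}

#' Class-dependent signal model for the synthetic generator
#'
#' Synthetic sessions carry a mu-band oscillation on the motor channels
#' F3/FC5 (left hemisphere) and F4/FC6 (right hemisphere) on top of
#' autocorrelated background noise. During an imagery cue the
#' oscillation amplitude is lateralised: class 1 (think left) scales the
#' left-hemisphere pair by `1 + contrast`, class 2 the right-hemisphere
#' pair; rest (class 0) keeps the baseline amplitude everywhere. With
#' `contrast = 0` all classes are statistically identical (the null
#' model). This structure is invented for testing: it emulates
#' lateralised sensorimotor-rhythm amplitude changes, not any recorded
#' data set.
#'
#' @param mu_freq oscillation frequency in Hz (default 10, mu band).
#' @param mu_amp baseline oscillation amplitude, a.u. (default 1).
#' @param contrast lateralisation contrast >= 0 (default 1).
#' @param noise_sd background noise standard deviation, a.u.
#'   (default 1).
#' @param ar background AR(1) coefficient in [0, 1) giving the noise a
#'   1/f-like spectral tilt (default 0.9).
#' @return a list of class `iqsa_signal_model`.
#' @export
signal_model <- function(mu_freq = 10, mu_amp = 1, contrast = 1,
                         noise_sd = 1, ar = 0.9) {
  stopifnot(mu_freq > 0, mu_amp >= 0, noise_sd >= 0, ar >= 0, ar < 1)
  if (contrast < 0) stop("contrast must be >= 0")
  structure(
    list(mu_freq = mu_freq, mu_amp = mu_amp, contrast = contrast,
         noise_sd = noise_sd, ar = ar),
    class = "iqsa_signal_model"
  )
}

# cue sequence of one run: alternates cross/arrow starting with a cross
run_schedule <- function(p) {
  kind <- character(0)
  a <- p$arrows_per_run; cr <- p$crosses_per_run
  while (a > 0L || cr > 0L) {
    if (cr > 0L) { kind <- c(kind, "cross"); cr <- cr - 1L }
    if (a > 0L) { kind <- c(kind, "arrow"); a <- a - 1L }
  }
  kind
}

#' Generate a labelled synthetic EEG session
#'
#' Deterministic under `seed`: cue schedule, arrow directions, noise
#' and oscillation phases are all drawn from the seeded RNG. Per-sample
#' labels follow the cue schedule exactly (0 during crosses, 1/2 during
#' arrows).
#'
#' @param paradigm a [paradigm_config()].
#' @param model a [signal_model()].
#' @param seed integer RNG seed.
#' @return an [eeg_recording()] with a `schedule` attribute (data frame
#'   of per-trial run, kind, class, start sample and length) and a
#'   `trial_counts` attribute giving both per-run cue counts and the
#'   total trial count.
#' @export
generate_session <- function(paradigm = paradigm_config(),
                             model = signal_model(), seed = 1L) {
  p <- paradigm; m <- model
  stopifnot(inherits(p, "iqsa_paradigm"), inherits(m, "iqsa_signal_model"))
  set.seed(seed)
  fs <- p$sampling_rate
  n_cross <- round(p$cross_s * fs)
  n_arrow <- round(p$arrow_s * fs)
  left_ch <- intersect(c("F3", "FC5"), p$channels)
  right_ch <- intersect(c("F4", "FC6"), p$channels)
  sched <- list()
  segs <- list()
  pos <- 0L
  for (run in seq_len(p$runs)) {
    kind <- run_schedule(p)
    n_arr <- sum(kind == "arrow")
    dirs <- sample(rep(1:2, length.out = n_arr))
    ai <- 0L
    for (tr in seq_along(kind)) {
      if (kind[tr] == "arrow") {
        ai <- ai + 1L
        cls <- dirs[ai]; len <- n_arrow
      } else {
        cls <- 0L; len <- n_cross
      }
      sched[[length(sched) + 1L]] <- data.frame(
        run = run, kind = kind[tr], class = cls, start = pos, length = len)
      pos <- pos + len
    }
  }
  sched <- do.call(rbind, sched)
  n_total <- pos
  nch <- length(p$channels)
  # AR(1) background noise, unit marginal sd scaled to noise_sd
  data <- matrix(0, n_total, nch, dimnames = list(NULL, p$channels))
  if (m$noise_sd > 0) {
    innov_sd <- sqrt(1 - m$ar^2)
    for (j in seq_len(nch)) {
      data[, j] <- m$noise_sd *
        as.numeric(stats::filter(stats::rnorm(n_total, sd = innov_sd),
                                 m$ar, method = "recursive"))
    }
  }
  # lateralised mu-band oscillation on the motor channels
  osc_ch <- c(left_ch, right_ch)
  if (m$mu_amp > 0 && length(osc_ch)) {
    t_idx <- seq_len(n_total) - 1L
    for (i in seq_len(nrow(sched))) {
      cls <- sched$class[i]
      idx <- sched$start[i] + seq_len(sched$length[i])
      for (ch in osc_ch) {
        amp <- m$mu_amp
        if (cls == 1L && ch %in% left_ch) amp <- amp * (1 + m$contrast)
        if (cls == 2L && ch %in% right_ch) amp <- amp * (1 + m$contrast)
        phase <- stats::runif(1, 0, 2 * pi)
        data[idx, ch] <- data[idx, ch] +
          amp * sin(2 * pi * m$mu_freq * t_idx[idx] / fs + phase)
      }
    }
  }
  label <- integer(n_total)
  for (i in seq_len(nrow(sched))) {
    label[sched$start[i] + seq_len(sched$length[i])] <- sched$class[i]
  }
  rec <- eeg_recording(data, sampling_rate = fs, label = label)
  attr(rec, "schedule") <- sched
  attr(rec, "trial_counts") <- list(
    arrows_per_run = p$arrows_per_run,
    crosses_per_run = p$crosses_per_run,
    cue_periods = nrow(sched),
    arrow_trials = sum(sched$kind == "arrow")
  )
  rec
}

#' Generate Gaussian feature clusters (classifier test shortcut)
#'
#' Draws three class-conditional Gaussian clusters directly in the
#' (mean, variance, contrast, homogeneity) feature space, bypassing
#' signal generation. Centroids are displaced by `separation` (in units
#' of the within-cluster noise sd) along the mean/variance/homogeneity
#' axes; `separation = 0` gives three identical distributions (the
#' permutation-null case). Rows are clamped to the valid feature
#' region: variance >= 0, contrast = variance + mean^2 (so
#' contrast >= mean^2), 0 < homogeneity <= Ns.
#'
#' @param n_per_class rows per class (>= 10).
#' @param separation centroid separation in noise-sd units (>= 0).
#' @param seed integer RNG seed.
#' @param ns nominal number of modulus values per window (bounds the
#'   homogeneity feature; default 60).
#' @return an `iqsa_features` data frame with `3 * n_per_class` rows.
#' @export
generate_feature_clusters <- function(n_per_class, separation, seed = 1L,
                                      ns = 60L) {
  if (n_per_class < 10L) stop("n_per_class must be >= 10")
  if (separation < 0) stop("separation must be >= 0")
  set.seed(seed)
  rows <- lapply(0:2, function(cl) {
    mu <- pmax(stats::rnorm(n_per_class, 2 + separation * cl, 1), 0)
    s2 <- pmax(stats::rnorm(n_per_class, 1 + 0.5 * separation * cl, 0.5), 0)
    h_center <- ns / (2 + 0.5 * separation * cl)
    h <- pmin(pmax(stats::rnorm(n_per_class, h_center, 1), 1e-6), ns)
    data.frame(mean = mu, variance = s2, contrast = s2 + mu^2,
               homogeneity = h, label = cl)
  })
  out <- do.call(rbind, rows)
  out$start <- NA_integer_
  class(out) <- c("iqsa_features", "data.frame")
  out
}
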