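#' Sliding-window configuration
#'
#' Governs the superposed (overlapping) segmentation of the EEG stream
#' and the rotation displacement used to build the quaternion pair.
#'
#' @param ns window length in samples (default 64, i.e. 0.5 s at
#'   128 Hz). Typical values are 64 to 384 in steps of 64.
#' @param t_disp window displacement in samples; `t_disp < ns` gives
#'   superposed windows, `t_disp = ns` non-overlapping ones (default 64).
#' @param dt rotation displacement in samples between the quaternion
#'   stream and the vector stream it is rotated against (default 4).
#' @param sampling_rate sampling frequency in Hz (default 128).
#' @return an object of class `iqsa_window_config`.
#' @export
window_config <- function(ns = 64L, t_disp = 64L, dt = 4L,
                          sampling_rate = 128) {
  ns <- as.integer(ns); t_disp <- as.integer(t_disp); dt <- as.integer(dt)
  if (dt < 1L) stop("dt must be >= 1")
  if (ns <= dt) stop("window length ns must exceed dt")
  if (t_disp < 1L || t_disp > ns) stop("t_disp must satisfy 1 <= t_disp <= ns")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(
    list(ns = ns, t_disp = t_disp, dt = dt, sampling_rate = sampling_rate),
    class = "iqsa_window_config"
  )
}

#' Window start indices for superposed segmentation
#'
#' Starts are 0-based and windows are half-open `[start, start + ns)`:
#' `0, t_disp, 2 * t_disp, ...` while the window still fits, giving
#' `floor((signal_length - ns) / t_disp) + 1` windows.
#'
#' @param signal_length total number of samples.
#' @param cfg a [window_config()].
#' @return integer vector of 0-based start indices (empty, with a
#'   warning, when the signal is shorter than one window).
#' @export
segment_windows <- function(signal_length, cfg) {
  stopifnot(inherits(cfg, "iqsa_window_config"))
  signal_length <- as.integer(signal_length)
  if (signal_length < cfg$ns) {
    warning("signal (", signal_length, " samples) shorter than one window (",
            cfg$ns, "); no windows produced")
    return(integer(0))
  }
  seq.int(0L, signal_length - cfg$ns, by = cfg$t_disp)
}

#' Statistical features of one q_mod window
#'
#' Over the `Ns` modulus values of a window: mean `sum(q)/Ns`, contrast
#' `sum(q^2)/Ns` (second raw moment), variance `contrast - mean^2`, and
#' homogeneity `sum(1 / (1 + q^2))` (unnormalised, so `0 < H <= Ns`).
#'
#' @param q_mod numeric vector of modulus values, length >= 2.
#' @return named numeric vector `c(mean, variance, contrast, homogeneity)`.
#' @export
window_features <- function(q_mod) {
  ns <- length(q_mod)
  if (ns < 2L) stop("need at least 2 modulus values")
  mu <- sum(q_mod) / ns
  con <- sum(q_mod^2) / ns
  c(mean = mu, variance = con - mu^2, contrast = con,
    homogeneity = sum(1 / (1 + q_mod^2)))
}

#' Modulus stream for one window of 4 channels
#'
#' Convenience wrapper: builds the quaternion/vector pair with
#' displacement `dt` and returns the rotated-modulus series of length
#' `ns - dt`.
#'
#' @param window ns-by-4 numeric matrix (scalar channel first).
#' @param dt rotation displacement in samples.
#' @return numeric vector of length `ns - dt`.
#' @export
window_modulus <- function(window, dt = 4L) {
  s <- build_quaternion_streams(window, dt)
  rotation_modulus(s$q, s$r)
}

#' Build the window feature matrix from a labelled recording
#'
#' Segments the recording into superposed windows, keeps only
#' label-pure windows (all samples carry one non-missing class; windows
#' straddling a cue transition are dropped), and computes the four
#' quaternion-modulus features per window.
#'
#' When the recording is unlabelled (or `use_labels = FALSE`) every
#' window is kept and the label column is `NA`; this is the
#' prediction-only path.
#'
#' @param recording an [eeg_recording()].
#' @param cfg a [window_config()].
#' @param channels four channel names, scalar component first (default
#'   `c("F3", "F4", "FC5", "FC6")`).
#' @param use_labels drop label-impure windows and attach classes
#'   (default: whenever the recording has labels).
#' @return a data frame of class `iqsa_features` with columns
#'   `mean,variance,contrast,homogeneity,label` plus a `start` column of
#'   0-based window starts.
#' @export
build_feature_matrix <- function(recording, cfg = window_config(),
                                 channels = c("F3", "F4", "FC5", "FC6"),
                                 use_labels = !is.null(recording$label)) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(cfg, "iqsa_window_config"))
  if (length(channels) != 4L || anyDuplicated(channels)) {
    stop("channels must be 4 distinct names")
  }
  missing_ch <- setdiff(channels, colnames(recording$data))
  if (length(missing_ch)) {
    stop("channel(s) not present in recording: ",
         paste(missing_ch, collapse = ", "))
  }
  if (use_labels && is.null(recording$label)) {
    stop("recording carries no labels")
  }
  sig <- recording$data[, channels, drop = FALSE]
  starts <- segment_windows(nrow(sig), cfg)
  rows <- vector("list", length(starts))
  labs <- rep(NA_integer_, length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i] + seq_len(cfg$ns)
    if (use_labels) {
      wl <- recording$label[idx]
      if (anyNA(wl) || length(unique(wl)) != 1L) next
      labs[i] <- wl[1L]
    }
    keep[i] <- TRUE
    rows[[i]] <- window_features(window_modulus(sig[idx, , drop = FALSE],
                                                cfg$dt))
  }
  feat <- do.call(rbind, rows[keep])
  out <- as.data.frame(if (is.null(feat)) {
    matrix(numeric(0), ncol = 4L,
           dimnames = list(NULL, c("mean", "variance", "contrast",
                                   "homogeneity")))
  } else feat)
  out$label <- labs[keep]
  out$start <- starts[keep]
  class(out) <- c("iqsa_features", "data.frame")
  out
}

feature_columns <- c("mean", "variance", "contrast", "homogeneity")

#' Write / read a feature matrix as CSV
#'
#' Round-trips the columns `mean,variance,contrast,homogeneity,label`
#' (plus window `start`).
#'
#' @param features an `iqsa_features` data frame.
#' @param path CSV path.
#' @return `path` invisibly / the feature data frame.
#' @export
write_features <- function(features, path) {
  utils::write.csv(
    features[, c(feature_columns, "label", "start")], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(feature_columns %in% names(out)))
  out$label <- as.integer(out$label)
  class(out) <- c("iqsa_features", "data.frame")
  out
}
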