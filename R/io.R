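#' EEG recording container
#'
#' @param data numeric matrix, samples in rows, one named column per
#'   channel.
#' @param sampling_rate sampling frequency in Hz.
#' @param label optional per-sample integer class labels in \{0, 1, 2\}
#'   (`NA` allowed for unlabelled stretches).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate = 128, label = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(colnames(data)) || anyDuplicated(colnames(data))) {
    stop("channel columns must carry distinct names")
  }
  if (ncol(data) < 1L) stop("recording needs at least one channel")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  if (!is.null(label)) {
    if (length(label) != nrow(data)) {
      stop("label length must match the number of samples")
    }
    label <- as.integer(label)
    bad <- label[!is.na(label)]
    if (length(bad) && !all(bad %in% 0:2)) stop("labels must lie in {0, 1, 2}")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate, label = label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)%s\n",
    nrow(x$data), ncol(x$data), x$sampling_rate,
    nrow(x$data) / x$sampling_rate,
    if (is.null(x$label)) ", unlabelled" else ", labelled"
  ))
  cat("channels:", paste(colnames(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Read an EEG recording from CSV
#'
#' Expects a header `time,<channel names...>[,label]`. The `time` column
#' is ignored beyond ordering; a trailing `label` column, if present,
#' supplies per-sample classes. Missing channel values are linearly
#' interpolated (endpoints extended) and the count of interpolated cells
#' is reported as a warning. Ragged rows abort with the offending line
#' number.
#'
#' @param path CSV file path.
#' @param sampling_rate sampling frequency in Hz (the CSV stores no
#'   metadata; default 128).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, sampling_rate = 128) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged CSV row at line ", bad, " of ", path)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)
  if (cols[1L] != "time") stop("first CSV column must be 'time'")
  has_label <- cols[length(cols)] == "label"
  ch_cols <- setdiff(cols, c("time", if (has_label) "label"))
  if (!length(ch_cols)) stop("no channel columns found")
  data <- as.matrix(df[, ch_cols, drop = FALSE])
  storage.mode(data) <- "double"
  n_missing <- sum(is.na(data))
  if (n_missing > 0) {
    for (j in seq_len(ncol(data))) {
      col <- data[, j]
      if (anyNA(col)) {
        ok <- which(!is.na(col))
        if (!length(ok)) stop("channel ", ch_cols[j], " is entirely missing")
        data[, j] <- stats::approx(ok, col[ok], xout = seq_along(col),
                                   rule = 2)$y
      }
    }
    warning("interpolated ", n_missing, " missing channel value(s)")
  }
  label <- if (has_label) suppressWarnings(as.integer(df$label)) else NULL
  eeg_recording(data, sampling_rate = sampling_rate, label = label)
}

#' Write an EEG recording to CSV
#'
#' Inverse of [read_recording()]: columns `time,<channels...>,label`
#' (label column only when the recording is labelled).
#'
#' @param recording an [eeg_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- nrow(recording$data)
  df <- data.frame(time = (seq_len(n) - 1L) / recording$sampling_rate)
  df <- cbind(df, as.data.frame(recording$data))
  if (!is.null(recording$label)) df$label <- recording$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report or run result
#'
#' CSV uses the conventional column naming `ER,RT,S0,S1,S2,Sp0,Sp1,Sp2`;
#' JSON serialises all fields with a `schema_version` marker and stable
#' key order.
#'
#' @param report an object from [evaluate_predictions()] or [run_iqsa()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- if (inherits(report, "iqsa_report")) list(report)
          else if (inherits(report, "iqsa_run")) report$reports
          else stop("report must be an iqsa_report or iqsa_run")
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(ER = r$et, RT = r$rt,
               S0 = r$sensitivity[["0"]], S1 = r$sensitivity[["1"]],
               S2 = r$sensitivity[["2"]],
               Sp0 = r$specificity[["0"]], Sp1 = r$specificity[["1"]],
               Sp2 = r$specificity[["2"]])
  }))
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(schema_version = 1L, reports = tab)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read an evaluation report table written by [write_report()]
#'
#' @param path CSV or JSON path.
#' @return a data frame with columns `ER,RT,S0,S1,S2,Sp0,Sp1,Sp2`.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$reports)
  } else {
    utils::read.csv(path)
  }
}
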