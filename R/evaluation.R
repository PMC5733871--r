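#' Recognition rate, error rate and per-class sensitivity/specificity
#'
#' For true classes `c` and predictions `c_hat` over the class set
#' \{0, 1, 2\}: recognition rate `RT = #(c == c_hat) / #c`, error rate
#' `ET = 1 - RT`, per-class sensitivity
#' `S_d = #(c == d & c == c_hat) / #(c == d)` and specificity
#' `Sp_d = #(c != d & c == c_hat) / #(c != d)` (correct classification
#' among samples whose true class is not `d`). A class absent from the
#' truth gets `NA` sensitivity (undefined, never imputed as 0).
#'
#' @param truth,pred equal-length integer vectors with values in
#'   \{0, 1, 2\}.
#' @return an object of class `iqsa_report`: `rt`, `et`, named
#'   `sensitivity` and `specificity` vectors, the 3x3 `confusion` matrix
#'   (rows = truth) and `n`.
#' @export
evaluate_predictions <- function(truth, pred) {
  if (length(truth) != length(pred) || !length(truth)) {
    stop("truth and pred must be equal-length, non-empty")
  }
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (anyNA(truth) || anyNA(pred) ||
      !all(c(truth, pred) %in% 0:2)) {
    stop("labels must lie in {0, 1, 2}")
  }
  classes <- 0:2
  conf <- table(factor(truth, classes), factor(pred, classes))
  conf <- matrix(as.integer(conf), 3L, 3L,
                 dimnames = list(truth = classes, pred = classes))
  correct <- truth == pred
  rt <- mean(correct)
  sens <- spec <- stats::setNames(rep(NA_real_, 3L), classes)
  for (d in classes) {
    in_d <- truth == d
    if (any(in_d)) sens[as.character(d)] <- mean(correct[in_d])
    if (any(!in_d)) spec[as.character(d)] <- mean(correct[!in_d])
  }
  structure(
    list(rt = rt, et = 1 - rt, sensitivity = sens, specificity = spec,
         confusion = conf, n = length(truth)),
    class = "iqsa_report"
  )
}

#' @export
print.iqsa_report <- function(x, ...) {
  cat(sprintf("<iqsa_report> n = %d   RT = %.4f   ET = %.4f\n",
              x$n, x$rt, x$et))
  tab <- rbind(sensitivity = x$sensitivity, specificity = x$specificity)
  print(round(tab, 4))
  invisible(x)
}

#' Column summary statistics of a results table
#'
#' Mean, standard deviation (both the sample `n - 1` and population `n`
#' forms), minimum and maximum of every numeric column; rows are
#' typically subjects.
#'
#' @param table a data frame (or matrix) with >= 2 rows; non-numeric
#'   columns are ignored.
#' @return a data frame with one row per metric and columns
#'   `metric, mean, sd, sd_pop, min, max`.
#' @export
column_stats <- function(table) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[, num, drop = FALSE]
  if (nrow(table) < 2L) stop("need at least 2 rows")
  out <- data.frame(
    metric = names(table),
    mean = vapply(table, mean, numeric(1)),
    sd = vapply(table, stats::sd, numeric(1)),
    sd_pop = vapply(table, function(x) {
      sqrt(mean((x - mean(x))^2))
    }, numeric(1)),
    min = vapply(table, min, numeric(1)),
    max = vapply(table, max, numeric(1)),
    row.names = NULL
  )
  out
}

#' Friedman aligned-ranks comparison of algorithms across subjects
#'
#' Aligns the n-by-k accuracy matrix by subtracting each subject's row
#' mean, then ranks all `n * k` aligned values jointly (average ranks on
#' ties) and averages each algorithm's `n` ranks. Orientation: the
#' larger the observed value (the better the accuracy), the lower the
#' rank, so rank 1 goes to the single best aligned performance and the
#' best algorithm has the smallest average rank. The k average ranks
#' always sum to `k * (n * k + 1) / 2`.
#'
#' @param accuracy numeric n-by-k matrix or data frame, subjects in
#'   rows, algorithms in columns (no missing cells; n >= 2, k >= 2).
#' @return an object of class `iqsa_aligned_ranks`: named `avg_rank`,
#'   `n`, `k`, the `aligned` matrix and the joint `ranks` matrix.
#' @export
friedman_aligned_ranks <- function(accuracy) {
  x <- as.matrix(accuracy)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing cells are not allowed")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 algorithms")
  if (is.null(colnames(x))) colnames(x) <- paste0("alg", seq_len(k))
  aligned <- x - rowMeans(x)
  ranks <- matrix(rank(-aligned), n, k, dimnames = dimnames(x))
  structure(
    list(avg_rank = colMeans(ranks), n = n, k = k, aligned = aligned,
         ranks = ranks),
    class = "iqsa_aligned_ranks"
  )
}

#' @export
print.iqsa_aligned_ranks <- function(x, ...) {
  cat(sprintf("<iqsa_aligned_ranks> n = %d subjects, k = %d algorithms\n",
              x$n, x$k))
  ord <- order(x$avg_rank)
  for (i in ord) {
    cat(sprintf("  %-14s %.4f\n", names(x$avg_rank)[i], x$avg_rank[i]))
  }
  cat("(lower average rank = better accuracy)\n")
  invisible(x)
}
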