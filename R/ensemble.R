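#' @importFrom rpart rpart rpart.control
NULL

#' Base-learner settings for the boosting ensemble
#'
#' CART trees (Gini impurity, via \pkg{rpart}) are grown essentially to
#' purity by default: the 4-dimensional feature space keeps them small.
#'
#' @param minsplit minimum node size to attempt a split.
#' @param cp complexity parameter (0 = no cost-complexity pruning).
#' @param maxdepth maximum tree depth.
#' @return a list of class `iqsa_tree_control`.
#' @export
tree_control <- function(minsplit = 4L, cp = 0, maxdepth = 30L) {
  structure(list(minsplit = as.integer(minsplit), cp = cp,
                 maxdepth = as.integer(maxdepth)),
            class = "iqsa_tree_control")
}

#' Balanced stratified fit / validation / test split
#'
#' Every class is first downsampled to the minority-class count so the
#' partitions are class-balanced. Per class, `train_frac` of the rows go
#' to training and the rest to test; within training, `fit_frac` go to
#' tree fitting and the rest to validation (where per-tree reliability
#' is measured). Fractions are applied with `floor`, remainder to the
#' held-out side. Fully reproducible under `seed`.
#'
#' @param features an `iqsa_features` data frame with a `label` column.
#' @param seed integer RNG seed.
#' @param train_frac fraction of each class used for training
#'   (default 0.7; the rest is test).
#' @param fit_frac fraction of the training rows used to fit trees
#'   (default 0.8; the rest validates them).
#' @param min_per_class minimum rows required per class (default 10).
#' @return list with integer row-index vectors `fit`, `val`, `test`.
#' @export
make_split <- function(features, seed = NULL, train_frac = 0.7,
                       fit_frac = 0.8, min_per_class = 10L) {
  lab <- features$label
  if (anyNA(lab)) stop("split requires fully labelled features")
  for (cl in 0:2) {
    n_cl <- sum(lab == cl)
    if (n_cl == 0L) stop("class ", cl, " absent from the feature matrix")
    if (n_cl < min_per_class) {
      stop("class ", cl, " has only ", n_cl, " rows (need >= ",
           min_per_class, ")")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n_c <- min(table(lab))
  fit <- val <- test <- integer(0)
  for (cl in 0:2) {
    rows <- sample(which(lab == cl), n_c)
    n_train <- floor(train_frac * n_c)
    n_fit <- floor(fit_frac * n_train)
    fit <- c(fit, rows[seq_len(n_fit)])
    val <- c(val, rows[n_fit + seq_len(n_train - n_fit)])
    test <- c(test, rows[n_train + seq_len(n_c - n_train)])
  }
  list(fit = fit, val = val, test = test)
}

#' Boosting resample of the fit set
#'
#' Builds the training multiset for the next weak learner: all
#' correctly classified rows `G`, each misclassified row `B` twice, plus
#' the worst-classified rows of the original fit set (those misclassified
#' by the largest cumulative number of previous trees). If the multiset
#' exceeds the original fit-set size it is subsampled (without
#' replacement over multiset elements) back to that size. An empty `B`
#' returns `G` unchanged.
#'
#' @param fit_idx integer indices of the original fit set.
#' @param G,B indices correctly / incorrectly classified by the previous
#'   tree (disjoint, union = `fit_idx`).
#' @param worst indices of the worst-classified rows (may be empty).
#' @return an integer multiset of row indices.
#' @export
resample_boost <- function(fit_idx, G, B, worst = integer(0)) {
  if (length(intersect(G, B))) stop("G and B must be disjoint")
  if (!length(B)) return(G)
  multiset <- c(G, rep(B, 2L), worst)
  if (length(multiset) > length(fit_idx)) {
    multiset <- multiset[sample.int(length(multiset), length(fit_idx))]
  }
  multiset
}

# -- rpart <-> portable node list --------------------------------------
# Nodes are numbered in the rpart convention (children of n are 2n and
# 2n+1) and stored as a data frame: feature index (into the 4 feature
# columns), threshold, whether "x < threshold" routes left, and the leaf
# class. This makes trees JSON-portable and prediction rpart-free.

fit_tree <- function(data, classes, control) {
  df <- data[, feature_columns, drop = FALSE]
  df$.class <- factor(data$label, levels = classes)
  rpart(.class ~ mean + variance + contrast + homogeneity, data = df,
        method = "class",
        control = rpart.control(minsplit = control$minsplit,
                                cp = control$cp,
                                maxdepth = control$maxdepth,
                                maxcompete = 0L, maxsurrogate = 0L,
                                usesurrogate = 0L, xval = 0L))
}

tree_to_nodes <- function(fit, classes) {
  frame <- fit$frame
  ids <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  feature <- match(as.character(frame$var), feature_columns)
  threshold <- rep(NA_real_, nrow(frame))
  lt_left <- rep(NA, nrow(frame))
  if (any(!is_leaf)) {
    # maxcompete = maxsurrogate = 0 => one splits row per internal node,
    # in frame order
    sp <- fit$splits
    k <- 0L
    for (i in which(!is_leaf)) {
      k <- k + 1L
      threshold[i] <- sp[k, "index"]
      lt_left[i] <- sp[k, "ncat"] < 0
    }
  }
  data.frame(
    id = ids, is_leaf = is_leaf, feature = feature, threshold = threshold,
    lt_left = lt_left,
    class = as.integer(classes[frame$yval])
  )
}

predict_nodes <- function(nodes, X) {
  out <- integer(nrow(X))
  row_of <- function(id) match(id, nodes$id)
  walk <- function(i, idx) {
    if (!length(idx)) return(invisible())
    if (nodes$is_leaf[i]) {
      out[idx] <<- nodes$class[i]
      return(invisible())
    }
    x <- X[idx, nodes$feature[i]]
    left <- if (nodes$lt_left[i]) x < nodes$threshold[i]
            else x >= nodes$threshold[i]
    walk(row_of(2L * nodes$id[i]), idx[left])
    walk(row_of(2L * nodes$id[i] + 1L), idx[!left])
  }
  walk(1L, seq_len(nrow(X)))
  out
}

#' Train the boosted decision-tree ensemble
#'
#' Trees are trained sequentially: the first on the full fit set, each
#' subsequent one on the [resample_boost()] multiset emphasising rows
#' the previous tree misclassified (plus the cumulatively
#' worst-classified rows). Each tree's recognition rate `RT` and error
#' rate `ET = 1 - RT` are measured on the validation set and its
#' reliability weight is the normalised validation accuracy
#' `alpha_i = RT_i / sum(RT)`, so the weights sum to 1. With
#' `alpha = "adaboost"` the weights are instead
#' `log((1 - ET) / ET)`-style stage weights, renormalised to sum to 1.
#'
#' @param fit_data,val_data `iqsa_features` data frames (labelled) for
#'   tree fitting and per-tree validation.
#' @param n_trees number of trees (default 10).
#' @param seed integer RNG seed (resampling is the only stochastic step).
#' @param control an [tree_control()].
#' @param alpha `"reliability"` (default) or `"adaboost"`.
#' @return an object of class `iqsa_ensemble`: trees (portable node
#'   lists), `alpha`, per-tree `rt`/`et`, the class set and training
#'   metadata.
#' @export
train_ensemble <- function(fit_data, val_data, n_trees = 10L, seed = NULL,
                           control = tree_control(),
                           alpha = c("reliability", "adaboost")) {
  alpha <- match.arg(alpha)
  if (!nrow(fit_data) || !nrow(val_data)) stop("empty fit or validation set")
  if (anyNA(fit_data$label) || anyNA(val_data$label)) {
    stop("training requires fully labelled features")
  }
  if (!is.null(seed)) set.seed(seed)
  classes <- sort(unique(c(fit_data$label, val_data$label)))
  n <- nrow(fit_data)
  X_fit <- as.matrix(fit_data[, feature_columns])
  X_val <- as.matrix(val_data[, feature_columns])
  miss <- integer(n)
  current <- seq_len(n)
  trees <- vector("list", n_trees)
  rt <- et <- numeric(n_trees)
  for (i in seq_len(n_trees)) {
    fit <- fit_tree(fit_data[current, , drop = FALSE], classes, control)
    nodes <- tree_to_nodes(fit, classes)
    trees[[i]] <- nodes
    pred_val <- predict_nodes(nodes, X_val)
    rt[i] <- mean(pred_val == val_data$label)
    et[i] <- 1 - rt[i]
    if (i < n_trees) {
      pred_fit <- predict_nodes(nodes, X_fit)
      wrong <- pred_fit != fit_data$label
      miss[wrong] <- miss[wrong] + 1L
      ord <- order(miss, decreasing = TRUE)
      cand <- ord[miss[ord] > 0L]
      worst <- cand[seq_len(min(length(cand), ceiling(0.1 * n)))]
      current <- resample_boost(seq_len(n), which(!wrong), which(wrong),
                                worst)
    }
  }
  if (all(rt == 0)) stop("degenerate data: every tree has zero accuracy")
  a <- if (alpha == "reliability") rt / sum(rt) else {
    eps <- pmin(pmax(et, 1e-9), 1 - 1e-9)
    w <- pmax(log((1 - eps) / eps), 0)
    if (sum(w) == 0) rep(1 / n_trees, n_trees) else w / sum(w)
  }
  structure(
    list(trees = trees, alpha = a, rt = rt, et = et, classes = classes,
         n_trees = n_trees, seed = seed, alpha_scheme = alpha,
         control = control),
    class = "iqsa_ensemble"
  )
}

#' @export
print.iqsa_ensemble <- function(x, ...) {
  cat(sprintf("<iqsa_ensemble> %d trees, classes {%s}\n", x$n_trees,
              paste(x$classes, collapse = ", ")))
  cat("validation RT:", sprintf("%.3f", x$rt), "\n")
  cat("alpha:        ", sprintf("%.3f", x$alpha), "\n")
  invisible(x)
}

#' Predict classes by weighted majority vote
#'
#' Each tree votes for one class per row; votes are weighted by the
#' tree's reliability `alpha` and the arg-max class wins. Exact ties are
#' broken deterministically towards the lowest class id.
#'
#' @param object an `iqsa_ensemble`.
#' @param newdata a feature data frame with the four feature columns.
#' @param ... unused.
#' @return list with `class` (integer vector) and `scores` (rows x
#'   classes matrix of summed weights).
#' @export
predict.iqsa_ensemble <- function(object, newdata, ...) {
  miss_col <- setdiff(feature_columns, names(newdata))
  if (length(miss_col)) {
    stop("newdata lacks feature column(s): ", paste(miss_col, collapse = ", "))
  }
  X <- as.matrix(newdata[, feature_columns])
  k <- length(object$classes)
  scores <- matrix(0, nrow(X), k, dimnames = list(NULL, object$classes))
  for (i in seq_along(object$trees)) {
    p <- predict_nodes(object$trees[[i]], X)
    scores[cbind(seq_len(nrow(X)), match(p, object$classes))] <-
      scores[cbind(seq_len(nrow(X)), match(p, object$classes))] +
      object$alpha[i]
  }
  # columns are in ascending class order, so "first" = lowest class id
  cls <- object$classes[max.col(scores, ties.method = "first")]
  list(class = cls, scores = scores)
}

#' Serialise / load an ensemble as portable JSON
#'
#' Stores every tree as a flat node list (node id, feature index,
#' threshold, routing direction, leaf class) together with the alpha
#' vector, class set, seed and base-learner settings, under a
#' `schema_version` marker. Reloading reproduces predictions exactly.
#'
#' @param model an `iqsa_ensemble`.
#' @param path JSON file path.
#' @return `path` invisibly / the restored `iqsa_ensemble`.
#' @export
write_ensemble <- function(model, path) {
  stopifnot(inherits(model, "iqsa_ensemble"))
  payload <- list(
    schema_version = 1L,
    classes = model$classes, alpha = model$alpha, rt = model$rt,
    et = model$et, n_trees = model$n_trees, seed = model$seed,
    alpha_scheme = model$alpha_scheme,
    control = unclass(model$control),
    trees = model$trees
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(p$n_trees), function(i) {
    nd <- as.data.frame(p$trees[[i]])
    nd$id <- as.integer(nd$id); nd$class <- as.integer(nd$class)
    nd$feature <- as.integer(nd$feature)
    nd
  })
  structure(
    list(trees = trees, alpha = as.numeric(p$alpha), rt = as.numeric(p$rt),
         et = as.numeric(p$et), classes = as.integer(p$classes),
         n_trees = as.integer(p$n_trees),
         seed = if (is.null(p$seed)) NULL else as.integer(p$seed),
         alpha_scheme = p$alpha_scheme,
         control = structure(p$control, class = "iqsa_tree_control")),
    class = "iqsa_ensemble"
  )
}
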