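test_that("balanced split yields the expected partition sizes", {
  f <- generate_feature_clusters(100, separation = 3, seed = 1)
  split <- make_split(f, seed = 5)
  expect_length(split$fit, 168)   # 3 * floor(0.8 * floor(0.7 * 100))
  expect_length(split$val, 42)
  expect_length(split$test, 90)
  all_idx <- c(split$fit, split$val, split$test)
  expect_equal(anyDuplicated(all_idx), 0)
  # balanced: 56/14/30 per class
  for (part in split) {
    expect_equal(as.vector(table(f$label[part])),
                 rep(length(part) / 3L, 3L))
  }
  # reproducible under seed
  split2 <- make_split(f, seed = 5)
  expect_identical(split, split2)
  split3 <- make_split(f, seed = 6)
  expect_false(identical(split, split3))
})

test_that("split rejects absent or tiny classes by name", {
  f <- generate_feature_clusters(30, separation = 1, seed = 2)
  f_missing <- f[f$label != 2, ]
  expect_error(make_split(f_missing, seed = 1), "class 2 absent")
  f_small <- f[c(which(f$label != 2), which(f$label == 2)[1:3]), ]
  expect_error(make_split(f_small, seed = 1), "class 2 has only 3")
})

test_that("boosting resample doubles the misclassified rows and caps size", {
  set.seed(31)
  fit_idx <- 1:100
  G <- 1:80; B <- 81:100
  out <- resample_boost(fit_idx, G, B)
  expect_length(out, 100)  # min(80 + 40, 100)
  expect_true(all(out %in% fit_idx))
  # uncapped case keeps exact multiplicities
  out2 <- resample_boost(1:200, G, B)
  expect_length(out2, 120)
  expect_equal(sum(out2 %in% B), 40)
  expect_equal(sum(out2 %in% G), 80)
  # perfect tree: fit set unchanged
  expect_identical(resample_boost(fit_idx, G = fit_idx, B = integer(0)),
                   fit_idx)
  # everything misclassified: doubled then capped back to fit size
  out3 <- resample_boost(fit_idx, G = integer(0), B = fit_idx)
  expect_length(out3, 100)
  expect_error(resample_boost(fit_idx, G = 1:10, B = 10:20), "disjoint")
})

test_that("ensemble trained on separable clusters is accurate and normalised", {
  f <- generate_feature_clusters(60, separation = 10, seed = 7)
  split <- make_split(f, seed = 7)
  model <- train_ensemble(f[split$fit, ], f[split$val, ], n_trees = 10,
                          seed = 7)
  expect_length(model$alpha, 10)
  expect_equal(sum(model$alpha), 1, tolerance = 1e-9)
  expect_equal(model$rt + model$et, rep(1, 10), tolerance = 1e-12)
  expect_true(all(model$rt >= 0.9))
  pred <- predict(model, f[split$test, ])
  expect_gt(mean(pred$class == f$label[split$test]), 0.95)
})

test_that("a one-tree ensemble is a plain decision tree with weight 1", {
  f <- generate_feature_clusters(30, separation = 5, seed = 8)
  split <- make_split(f, seed = 8)
  model <- train_ensemble(f[split$fit, ], f[split$val, ], n_trees = 1,
                          seed = 8)
  expect_equal(model$alpha, 1)
  # cross-check the portable tree against rpart's own predictions
  ctrl <- tree_control()
  df <- f[split$fit, c("mean", "variance", "contrast", "homogeneity")]
  df$.class <- factor(f$label[split$fit], levels = 0:2)
  ref <- rpart::rpart(.class ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = ctrl$minsplit, cp = ctrl$cp,
                        maxdepth = ctrl$maxdepth, maxcompete = 0,
                        maxsurrogate = 0, usesurrogate = 0, xval = 0))
  newx <- f[split$test, c("mean", "variance", "contrast", "homogeneity")]
  ref_pred <- as.integer(as.character(predict(ref, newx, type = "class")))
  expect_equal(predict(model, f[split$test, ])$class, ref_pred)
})

test_that("training is reproducible and serialises losslessly to JSON", {
  f <- generate_feature_clusters(40, separation = 2, seed = 9)
  split <- make_split(f, seed = 9)
  m1 <- train_ensemble(f[split$fit, ], f[split$val, ], seed = 123)
  m2 <- train_ensemble(f[split$fit, ], f[split$val, ], seed = 123)
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$alpha, m2$alpha)
  p1 <- predict(m1, f[split$test, ])
  expect_identical(p1, predict(m2, f[split$test, ]))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(m1, path)
  m3 <- read_ensemble(path)
  p3 <- predict(m3, f[split$test, ])
  expect_identical(p1$class, p3$class)
  expect_equal(p1$scores, p3$scores)
  expect_equal(m3$alpha, m1$alpha)
})

test_that("weighted vote matches a brute-force tally and breaks ties low", {
  # hand-built stumps: split on `mean` at 0, vote fixed classes
  stump <- function(cls_left, cls_right) {
    data.frame(id = 1:3,
               is_leaf = c(FALSE, TRUE, TRUE),
               feature = c(1L, NA, NA),
               threshold = c(0, NA, NA),
               lt_left = c(TRUE, NA, NA),
               class = c(NA, cls_left, cls_right))
  }
  mk <- function(trees, alpha) {
    structure(list(trees = trees, alpha = alpha, rt = alpha, et = 1 - alpha,
                   classes = 0:2, n_trees = length(trees), seed = NULL,
                   alpha_scheme = "reliability", control = tree_control()),
              class = "iqsa_ensemble")
  }
  X <- data.frame(mean = c(-1, 1), variance = 0, contrast = 1,
                  homogeneity = 1)
  # unanimous vote
  m <- mk(list(stump(2L, 2L), stump(2L, 2L)), c(0.5, 0.5))
  p <- predict(m, X)
  expect_equal(p$class, c(2L, 2L))
  expect_equal(unname(p$scores[, "2"]), c(1, 1))
  # exact tie between classes 0 and 1 -> lowest class id wins
  m2 <- mk(list(stump(0L, 0L), stump(1L, 1L)), c(0.5, 0.5))
  expect_equal(predict(m2, X)$class, c(0L, 0L))
  # random ensembles against an explicit tally oracle
  set.seed(33)
  for (rep in 1:20) {
    n_tr <- sample(2:6, 1)
    votes <- matrix(sample(0:2, n_tr * 2, replace = TRUE), n_tr, 2)
    alpha <- runif(n_tr); alpha <- alpha / sum(alpha)
    trees <- lapply(seq_len(n_tr), function(i) {
      stump(votes[i, 1], votes[i, 2])
    })
    p <- predict(mk(trees, alpha), X)
    for (row in 1:2) {
      tally <- vapply(0:2, function(cl) {
        sum(alpha[votes[, row] == cl])
      }, numeric(1))
      expect_equal(unname(p$scores[row, ]), tally, tolerance = 1e-12)
      expect_equal(p$class[row], (0:2)[which.max(tally)])
    }
  }
})

test_that("uniform weights reduce the vote to a plain majority", {
  f <- generate_feature_clusters(40, separation = 1.5, seed = 10)
  split <- make_split(f, seed = 10)
  model <- train_ensemble(f[split$fit, ], f[split$val, ], n_trees = 5,
                          seed = 10)
  model$alpha <- rep(1 / 5, 5)
  p <- predict(model, f[split$test, ])
  # majority oracle from per-tree votes
  X <- as.matrix(f[split$test, c("mean", "variance", "contrast",
                                 "homogeneity")])
  votes <- sapply(model$trees, function(tr) iqsa:::predict_nodes(tr, X))
  maj <- apply(votes, 1, function(v) {
    counts <- tabulate(v + 1L, 3L)
    (0:2)[which.max(counts)]
  })
  expect_equal(p$class, maj)
})

test_that("boosting does not fall below the best single tree on separable data", {
  for (seed in 1:20) {
    f <- generate_feature_clusters(30, separation = 6, seed = seed)
    split <- make_split(f, seed = seed)
    model <- train_ensemble(f[split$fit, ], f[split$val, ], n_trees = 5,
                            seed = seed)
    val <- f[split$val, ]
    ens_rt <- mean(predict(model, val)$class == val$label)
    expect_gte(ens_rt, max(model$rt) - 0.05)
  }
})

test_that("label-shuffled features give chance-level accuracy", {
  rts <- vapply(1:20, function(seed) {
    f <- generate_feature_clusters(50, separation = 0, seed = seed)
    split <- make_split(f, seed = seed)
    model <- train_ensemble(f[split$fit, ], f[split$val, ], n_trees = 5,
                            seed = seed)
    test <- f[split$test, ]
    mean(predict(model, test)$class == test$label)
  }, numeric(1))
  ci <- mean(rts) + c(-2, 2) * sd(rts) / sqrt(length(rts))
  expect_gt(1 / 3, ci[1])
  expect_lt(1 / 3, ci[2])
})
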