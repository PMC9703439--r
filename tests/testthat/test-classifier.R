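make_features <- function(n_pos, n_neg, p = 6, sep = 0, seed = 1,
                          cols = NULL) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_pos * p, mean = sep), n_pos),
             matrix(rnorm(n_neg * p), n_neg))
  if (is.null(cols)) cols <- paste0("f", seq_len(p))
  colnames(X) <- cols
  df <- as.data.frame(X)
  df$subject_id <- sprintf("s%02d", seq_len(n_pos + n_neg))
  df$group <- rep(c("depressed", "non-depressed"), c(n_pos, n_neg))
  df
}

test_that("standardization uses training statistics only", {
  set.seed(60)
  train <- matrix(rnorm(30, 5, 3), 10)
  colnames(train) <- c("a", "b", "c")
  test <- matrix(colMeans(train), 1)  # the train mean row
  colnames(test) <- colnames(train)
  std <- standardize_features(train, test)
  expect_equal(unname(colMeans(std$train)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(std$train, 2, sd)), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(unname(std$test[1, ]), rep(0, 3), tolerance = 1e-12)

  # hand z-scores on a 3-row table
  h <- matrix(c(1, 2, 6, 0, 0, 3), 3)
  colnames(h) <- c("x", "y")
  sh <- standardize_features(h)
  expect_equal(sh$train[, "x"], (h[, "x"] - 3) / sd(h[, "x"]),
               ignore_attr = TRUE)

  # constant column flagged, scaled by 1
  cc <- cbind(k = rep(2, 4), v = 1:4)
  expect_warning(sc <- standardize_features(cc), "constant")
  expect_equal(unname(sc$train[, "k"]), rep(0, 4))
})

test_that("class weights follow N / (K * n_k)", {
  w <- class_weights(rep(c("non-depressed", "depressed"), c(103, 32)))
  expect_equal(unname(w["non-depressed"]), 135 / (2 * 103))
  expect_equal(unname(w["depressed"]), 135 / (2 * 32))
  expect_equal(unname(round(w, 3)), c(2.109, 0.655))

  wb <- class_weights(rep(c("a", "b"), each = 10))
  expect_equal(unname(wb), c(1, 1))
  # weighted counts rebalance to N per class set
  expect_equal(sum(w * c(32, 103)[match(names(w), c("depressed",
                                                    "non-depressed"))]),
               135)
})

test_that("the squared-hinge solver matches an independent optimiser", {
  set.seed(61)
  for (rep in 1:6) {
    n <- 20; p <- 5
    X <- matrix(rnorm(n * p), n)
    y <- sign(rnorm(n)); y[y == 0] <- 1
    C <- 10^sample(-2:2, 1)
    sw <- runif(n, 0.5, 2)
    fit <- fit_linear_svm(X, y, C, sw)
    obj <- function(beta) {
      f <- X %*% beta[1:p] + beta[p + 1]
      0.5 * sum(beta^2) + C * sum(sw * pmax(0, 1 - y * f)^2)
    }
    o <- optim(rep(0, p + 1), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    expect_lt(max(abs(c(fit$w, fit$b) - o$par)), 1e-5)
    expect_lte(fit$objective, o$value + 1e-8)
  }
})

test_that("RFE keeps informative features and is the identity at full size", {
  set.seed(62)
  n <- 40
  sep_feat <- c(rnorm(n / 2, 3), rnorm(n / 2, -3))
  X <- cbind(sep = sep_feat, matrix(rnorm(n * 7), n))
  colnames(X) <- c("sep", paste0("noise", 1:7))
  y <- rep(c(1, -1), each = n / 2)
  survived <- replicate(20, {
    Xp <- X + matrix(rnorm(length(X), sd = .01), nrow(X))
    "sep" %in% rfe_select(Xp, y, 4)
  })
  expect_true(all(survived))

  expect_equal(rfe_select(X, y, ncol(X)), colnames(X))
  sel6 <- rfe_select(X, y, 6)
  expect_length(sel6, 6)
})

test_that("cost grid search is stratified with smallest-C tie-breaks", {
  set.seed(63)
  # separable training data: every C is perfect -> smallest C returned
  X <- cbind(c(rnorm(9, 5), rnorm(9, -5)), rnorm(18))
  colnames(X) <- c("a", "b")
  y <- rep(c(1, -1), each = 9)
  gs <- grid_search_C(X, y, 10^(-3:3), 3)
  expect_equal(gs$C, 1e-3)
  expect_equal(max(gs$accuracy), 1)

  gs1 <- grid_search_C(X, y, 10, 3)
  expect_equal(gs1$C, 10)

  # stratification: each fold's class counts within 1 of proportional
  yy <- rep(c(1, -1), c(8, 13))
  folds <- moodtrf:::.stratified_folds(yy, 3)
  for (f in 1:3) {
    expect_lte(abs(sum(yy[folds == f] == 1) - 8 / 3), 1)
    expect_lte(abs(sum(yy[folds == f] == -1) - 13 / 3), 1)
  }
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(compute_auc(1:10, rep(c(0, 1), each = 5) == 1), 1)
  set.seed(64)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    scores <- sample(1:5, n, replace = TRUE)  # force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(compute_auc(scores, labels), auc_pairs(scores, labels))
  }
  # cross-check against an established implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(65)
    s <- rnorm(30)
    l <- sample(c(0, 1), 30, replace = TRUE)
    expect_equal(compute_auc(s, l),
                 as.numeric(suppressMessages(pROC::auc(l, s,
                                                       direction = "<"))))
  }
})

test_that("confusion rates reproduce the count ratios", {
  r <- confusion_rates(tp = 25, fn = 7, tn = 74, fp = 29)
  expect_equal(round(r$tpr, 3), 0.781)
  expect_equal(round(r$tnr, 3), 0.718)
})

test_that("LOOCV produces one fold per subject without information leakage", {
  ft <- make_features(8, 10, sep = 2, seed = 66)
  cfg <- classifier_config("combination", n_selected = 4, seed = 5)
  # use the generic columns directly via a custom config surface
  cols <- paste0("f", 1:6)
  X <- as.matrix(ft[, cols])
  y <- ifelse(ft$group == "depressed", 1, -1)
  set.seed(cfg$seed)
  res <- moodtrf:::.loocv_scores(X, y, cfg, collect = TRUE)
  expect_length(res$scores, 18)
  expect_length(res$folds, 18)

  # mutate the held-out subject's features: fold-internal parameters for
  # that fold must not change
  X2 <- X
  X2[3, ] <- X2[3, ] + 100
  set.seed(cfg$seed)
  res2 <- moodtrf:::.loocv_scores(X2, y, cfg, collect = TRUE)
  expect_identical(res$folds[[3]]$selected, res2$folds[[3]]$selected)
  expect_identical(res$folds[[3]]$C, res2$folds[[3]]$C)
  expect_equal(res$folds[[3]]$w, res2$folds[[3]]$w)

  # strongly separated features classify perfectly
  fts <- make_features(8, 10, sep = 6, seed = 67,
                       cols = feature_columns("subjective_only"))
  rep_s <- loocv_classify(fts, classifier_config("subjective_only",
                                                 seed = 2))
  expect_equal(rep_s$auc, 1)
  expect_equal(rep_s$tpr, 1)
  expect_equal(rep_s$tnr, 1)
  expect_equal(sum(rep_s$confusion), 18)
})

test_that("label-independent features give chance-level AUC", {
  set.seed(68)
  aucs <- replicate(12, {
    ft <- make_features(6, 8, sep = 0, seed = sample.int(1e6, 1),
                        cols = feature_columns("subjective_only"))
    loocv_classify(ft, classifier_config("subjective_only",
                                         seed = sample.int(1e6, 1)))$auc
  })
  expect_gt(median(aucs), 0.25)
  expect_lt(median(aucs), 0.75)
})

test_that("permutation p has the correct floor and degenerate behaviour", {
  ft <- make_features(6, 8, sep = 6, seed = 69,
                      cols = feature_columns("subjective_only"))
  cfg <- classifier_config("subjective_only", seed = 3)
  rep0 <- loocv_classify(ft, cfg)
  expect_equal(rep0$auc, 1)
  pt <- permutation_test(ft, cfg, n_perm = 19, observed_auc = rep0$auc)
  # separable data: every null AUC below the observed 1.0 unless a
  # permutation reproduces the labels; floor = 1/(n_perm + 1)
  expect_gte(pt$p, 1 / 20)
  expect_equal(pt$p, (sum(pt$null_auc >= 1) + 1) / 20)

  # observed equal to every null -> p = 1
  fake <- permutation_test(ft, cfg, n_perm = 19, observed_auc = 0)
  expect_equal(fake$p, 1)

  expect_error(permutation_test(ft, cfg, n_perm = 0), "n_perm")
})

test_that("coefficient aggregation zero-fills unselected features and normalises", {
  folds <- list(list(w = c(a = 2, b = 1)), list(w = c(a = -2, b = 0.5)))
  agg <- aggregate_coefficients(folds, c("a", "b", "c"))
  expect_equal(agg$mean_abs_coef, c(2, 0.75, 0))
  expect_equal(agg$normalized, c(1, 0.375, 0))
  expect_equal(agg$feature, c("a", "b", "c"))

  # hand case with three folds
  f3 <- list(list(w = c(x = 1)), list(w = c(y = 3)), list(w = c(x = 2)))
  agg3 <- aggregate_coefficients(f3, c("x", "y"))
  expect_equal(agg3$mean_abs_coef, c(1, 1))
})

test_that("median AUC rises with the injected effect scale", {
  # monotone difficulty on feature-level surrogates: separation 0 / 0.8 / 3
  seps <- c(0, 0.8, 3)
  med <- vapply(seps, function(sp) {
    aucs <- vapply(1:7, function(s) {
      ft <- make_features(6, 9, sep = sp, seed = 600 + s,
                          cols = feature_columns("subjective_only"))
      loocv_classify(ft, classifier_config("subjective_only",
                                           seed = s))$auc
    }, 0)
    median(aucs)
  }, 0)
  expect_true(all(diff(med) >= 0))
  expect_gt(med[3], 0.9)
})
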