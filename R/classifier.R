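#' Classifier configuration
#'
#' Defaults reproduce the screening protocol: recursive feature elimination
#' to 6 features (EEG-only and combination sets; the 6-feature subjective
#' set is used as-is), cost grid 10^-3..10^3 in decade steps selected by
#' stratified three-fold cross-validation of the training data, balanced
#' class weighting, squared-hinge loss with L2 penalty, and 1000 label
#' permutations for the significance test.
#'
#' @param feature_set `"combination"`, `"eeg_only"` or `"subjective_only"`.
#' @param n_selected features kept by RFE (ignored for subjective_only).
#' @param C_grid candidate cost parameters.
#' @param inner_folds stratified folds for the cost search.
#' @param n_permutations label randomisations for [permutation_test()].
#' @param seed master seed; fans out to inner-fold shuffling and the
#'   permutation order.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(feature_set = c("combination", "eeg_only",
                                              "subjective_only"),
                              n_selected = 6L, C_grid = 10^(-3:3),
                              inner_folds = 3L, n_permutations = 1000L,
                              seed = 1L) {
  feature_set <- match.arg(feature_set)
  stopifnot(length(C_grid) >= 1, n_selected >= 1, inner_folds >= 2)
  structure(list(feature_set = feature_set,
                 n_selected = as.integer(n_selected),
                 C_grid = sort(as.numeric(C_grid)),
                 inner_folds = as.integer(inner_folds),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Standardize features with training statistics
#'
#' Per-column z-scoring; means and SDs come from the training rows only and
#' are applied unchanged to the test rows. Constant columns (SD 0) are
#' flagged and scaled by 1.
#'
#' @param train numeric matrix (rows = subjects).
#' @param apply_to optional matrix transformed with the training
#'   statistics.
#' @return List: train, test (or NULL), center, scale, constant (logical).
#' @export
standardize_features <- function(train, apply_to = NULL) {
  stopifnot(nrow(train) >= 2)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  constant <- scl == 0
  scl[constant] <- 1
  if (any(constant)) {
    warning("constant feature column(s) left unscaled: ",
            paste(colnames(train)[constant], collapse = ", "))
  }
  zt <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  za <- if (!is.null(apply_to)) {
    sweep(sweep(apply_to, 2, ctr, ), 2, scl, "/")
  }
  list(train = zt, test = za, center = ctr, scale = scl,
       constant = constant)
}

#' Balanced class weights
#'
#' `weight_k = N / (K * n_k)`: the total sample count over the number of
#' classes times the class size, so the minority class carries
#' proportionally larger error cost.
#'
#' @param labels factor or character vector of training labels.
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  n <- sum(tab)
  k <- length(tab)
  setNames(as.numeric(n / (k * tab)), names(tab))
}

#' Fit a class-weighted squared-hinge L2 linear classifier
#'
#' Minimises `0.5 ||(w, b)||^2 + C sum_i cw_i max(0, 1 - y_i f_i)^2` by
#' Newton iteration (the objective is convex and piecewise quadratic).
#' `y` must be coded +1 (positive class) / -1.
#'
#' @param X numeric matrix (rows = samples).
#' @param y numeric +1/-1 labels.
#' @param C cost parameter.
#' @param sample_weight per-sample weights (typically the class weight of
#'   each sample's class); default all 1.
#' @return List: w (coefficients), b (intercept), objective, iterations.
#' @export
fit_linear_svm <- function(X, y, C, sample_weight = rep(1, length(y))) {
  stopifnot(all(y %in% c(-1, 1)), length(y) == nrow(X),
            length(sample_weight) == length(y), C > 0)
  cpp_sqhinge_fit(as.matrix(X), as.numeric(y), C,
                  as.numeric(sample_weight))
}

#' Recursive feature elimination
#'
#' Iteratively fits the linear classifier and drops the feature with the
#' smallest absolute coefficient, one per iteration, until `n_keep` remain.
#' Features are assumed already standardized; no re-standardization between
#' iterations.
#'
#' @param X standardized training matrix with column names.
#' @param y +1/-1 labels.
#' @param n_keep number of surviving features.
#' @param C cost used for the elimination fits (default 1).
#' @param sample_weight per-sample weights.
#' @return Character vector of selected feature names (original column
#'   order).
#' @export
rfe_select <- function(X, y, n_keep, C = 1,
                       sample_weight = rep(1, length(y))) {
  stopifnot(n_keep <= ncol(X), !is.null(colnames(X)))
  keep <- colnames(X)
  while (length(keep) > n_keep) {
    fit <- fit_linear_svm(X[, keep, drop = FALSE], y, C, sample_weight)
    drop_i <- which.min(abs(fit$w))
    keep <- keep[-drop_i]
  }
  colnames(X)[colnames(X) %in% keep]
}

# deterministic stratified fold assignment (class-wise round-robin after a
# seeded shuffle); fold sizes per class differ by at most one
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Grid search for the cost parameter
#'
#' Stratified k-fold cross-validation of the training data; candidate with
#' the highest mean fold accuracy wins, ties break toward the smallest C.
#' Fits are class-weighted; accuracy is plain (unweighted).
#'
#' @param X standardized training matrix.
#' @param y +1/-1 labels (each class needs >= `inner_folds` members).
#' @param C_grid candidate costs.
#' @param inner_folds number of folds.
#' @return List: C (selected), accuracy (per candidate).
#' @export
grid_search_C <- function(X, y, C_grid = 10^(-3:3), inner_folds = 3L) {
  stopifnot(min(table(y)) >= inner_folds)
  folds <- .stratified_folds(y, inner_folds)
  cw <- class_weights(factor(y))
  acc <- vapply(C_grid, function(C) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      sw <- cw[as.character(y[tr])]
      fit <- fit_linear_svm(X[tr, , drop = FALSE], y[tr], C, sw)
      pred <- sign(X[!tr, , drop = FALSE] %*% fit$w + fit$b)
      pred[pred == 0] <- 1
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, 0)
  best <- which(acc >= max(acc) - 1e-12)
  list(C = C_grid[min(best)], accuracy = acc)
}

# core LOOCV scorer used by both the public classifier and the permutation
# test; returns decision scores only (hot path)
.loocv_scores <- function(X, y, config, collect = FALSE) {
  n <- nrow(X)
  use_rfe <- config$feature_set != "subjective_only" &&
    config$n_selected < ncol(X)
  scores <- numeric(n)
  folds <- if (collect) vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    std <- standardize_features(X[tr, , drop = FALSE],
                                X[i, , drop = FALSE])
    ytr <- y[tr]
    cw <- class_weights(factor(ytr))
    sw <- cw[as.character(ytr)]
    feats <- colnames(X)
    Xtr <- std$train
    Xte <- std$test
    if (use_rfe) {
      feats <- rfe_select(Xtr, ytr, config$n_selected, C = 1, sw)
      Xtr <- Xtr[, feats, drop = FALSE]
      Xte <- Xte[, feats, drop = FALSE]
    }
    gs <- grid_search_C(Xtr, ytr, config$C_grid, config$inner_folds)
    fit <- fit_linear_svm(Xtr, ytr, gs$C, sw)
    scores[i] <- drop(Xte %*% fit$w + fit$b)
    if (collect) {
      folds[[i]] <- list(held_out = i, selected = feats, C = gs$C,
                         w = setNames(drop(fit$w), feats), b = fit$b)
    }
  }
  if (collect) list(scores = scores, folds = folds) else scores
}

#' Area under the ROC curve
#'
#' Probability that a random positive case outscores a random negative one,
#' ties counting one half (the normalised Mann-Whitney U statistic).
#'
#' @param scores numeric decision scores.
#' @param labels binary labels (1/TRUE = positive).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion rates
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return List: tpr = TP/(TP+FN), tnr = TN/(TN+FP).
#' @export
confusion_rates <- function(tp, fn, tn, fp) {
  list(tpr = tp / (tp + fn), tnr = tn / (tn + fp))
}

#' Leave-one-subject-out classification
#'
#' One subject is held out per fold; the remainder is standardized (fold
#' statistics only), reduced by RFE where the feature set calls for it,
#' the cost parameter is grid-searched in stratified inner folds, and the
#' class-weighted squared-hinge model scores the held-out subject. Decision
#' scores pooled over folds give the AUC; scores > 0 predict the depressed
#' class for the confusion counts.
#'
#' @param features feature table from [build_feature_table()] (or any
#'   data.frame with subject_id, group and the feature columns).
#' @param config a [classifier_config()].
#' @param positive_class label treated as positive (default
#'   `"depressed"`).
#' @return List of class `classification_report`: auc, tpr, tnr, confusion
#'   (tp, fn, tn, fp), scores, labels, folds (per-fold selection, C,
#'   coefficients), coefficients (aggregated; see
#'   [aggregate_coefficients()]).
#' @export
loocv_classify <- function(features, config = classifier_config(),
                           positive_class = "depressed") {
  cols <- feature_columns(config$feature_set)
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(features[, cols, drop = FALSE])
  y <- ifelse(features$group == positive_class, 1, -1)
  if (min(table(y)) < 2) stop("need >= 2 subjects per class")
  set.seed(config$seed)
  res <- .loocv_scores(X, y, config, collect = TRUE)
  pred <- ifelse(res$scores > 0, 1, -1)
  tp <- sum(pred == 1 & y == 1)
  fn <- sum(pred == -1 & y == 1)
  tn <- sum(pred == -1 & y == -1)
  fp <- sum(pred == 1 & y == -1)
  rates <- confusion_rates(tp, fn, tn, fp)
  structure(list(auc = compute_auc(res$scores, y == 1),
                 tpr = rates$tpr, tnr = rates$tnr,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 scores = res$scores, labels = y, folds = res$folds,
                 coefficients = aggregate_coefficients(res$folds, cols),
                 feature_set = config$feature_set),
            class = "classification_report")
}

#' Label-permutation significance test
#'
#' The full pipeline (in-fold standardization, RFE, cost search, weighted
#' fit) is re-run for each of `n_perm` label randomisations; each
#' randomisation permutes the subject labels once and reuses that
#' assignment across all of its LOOCV folds. The empirical p-value is
#' `(#\{null AUC >= observed\} + 1) / (n_perm + 1)`.
#'
#' @param features feature table.
#' @param config a [classifier_config()].
#' @param n_perm number of randomisations (default from `config`).
#' @param observed_auc observed AUC; recomputed via [loocv_classify()] when
#'   omitted.
#' @param positive_class positive label.
#' @return List: p, observed_auc, null_auc (vector of length `n_perm`).
#' @export
permutation_test <- function(features, config = classifier_config(),
                             n_perm = config$n_permutations,
                             observed_auc = NULL,
                             positive_class = "depressed") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  cols <- feature_columns(config$feature_set)
  X <- as.matrix(features[, cols, drop = FALSE])
  y <- ifelse(features$group == positive_class, 1, -1)
  if (is.null(observed_auc)) {
    observed_auc <- loocv_classify(features, config, positive_class)$auc
  }
  set.seed(config$seed + 1L)
  null_auc <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    s <- .loocv_scores(X, yp, config)
    compute_auc(s, yp == 1)
  }, 0)
  list(p = (sum(null_auc >= observed_auc) + 1) / (n_perm + 1),
       observed_auc = observed_auc, null_auc = null_auc)
}

#' Aggregate per-fold coefficients
#'
#' Mean absolute coefficient per feature across all LOOCV folds, features
#' never selected in a fold contributing zero there; min-max normalised to
#' \[0, 1\] for reporting.
#'
#' @param folds per-fold results from [loocv_classify()].
#' @param feature_names full feature name vector (defines the output
#'   order).
#' @return data.frame: feature, mean_abs_coef, normalized.
#' @export
aggregate_coefficients <- function(folds, feature_names) {
  acc <- setNames(numeric(length(feature_names)), feature_names)
  for (f in folds) {
    acc[names(f$w)] <- acc[names(f$w)] + abs(f$w)
  }
  m <- acc / length(folds)
  rng <- range(m)
  norm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  data.frame(feature = feature_names, mean_abs_coef = unname(m),
             normalized = unname(norm), stringsAsFactors = FALSE)
}
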