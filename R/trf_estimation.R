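#' Build a word-onset stimulus vector
#'
#' Binary impulse sequence at the EEG sampling rate: 1 at the sample nearest
#' each content-word onset (0-based sample index `round(onset * fs)`), 0
#' elsewhere. Onsets that collide on the same sample clip to a single 1.
#'
#' @param onsets onset times in seconds, within `[0, n_samples / fs)`.
#' @param fs sampling rate in Hz.
#' @param n_samples length of the vector.
#' @return Numeric 0/1 vector with attribute `fs`.
#' @export
build_stimulus_vector <- function(onsets, fs, n_samples) {
  idx <- round(onsets * fs) + 1L
  bad <- onsets < 0 | idx > n_samples
  if (any(bad)) {
    stop(sprintf("onset(s) out of range for %d samples at %g Hz: %s",
                 n_samples, fs, paste(format(onsets[bad]), collapse = ", ")))
  }
  s <- numeric(n_samples)
  s[idx] <- 1
  attr(s, "fs") <- fs
  s
}

#' Build the lagged design matrix for TRF estimation
#'
#' Column tau holds the stimulus delayed by tau samples (`X[t, j] =
#' s(t - tau_j)`), zero-padded outside the trial. At 200 Hz the default
#' -100..800 ms range gives 181 columns on a 5 ms grid. The matrix is
#' stored sparse: an impulse train with w onsets has only `w * n_lags`
#' non-zeros.
#'
#' @param stim stimulus vector from [build_stimulus_vector()].
#' @param lag_range_ms length-2 lag range in ms (default -100..800).
#' @param fs sampling rate; taken from `stim`'s attribute when omitted.
#' @return A `Matrix::sparseMatrix` (samples x lags) with attribute
#'   `lag_ms`.
#' @export
build_lagged_design <- function(stim, lag_range_ms = c(-100, 800), fs = NULL) {
  if (is.null(fs)) fs <- attr(stim, "fs")
  stopifnot(!is.null(fs))
  lag_samp <- seq(round(lag_range_ms[1] * fs / 1000),
                  round(lag_range_ms[2] * fs / 1000))
  lag_ms <- lag_samp * 1000 / fs
  n <- length(stim)
  ones <- which(stim != 0)
  ii <- jj <- integer(0)
  if (length(ones)) {
    grid <- expand.grid(t0 = ones, j = seq_along(lag_samp))
    rows <- grid$t0 + lag_samp[grid$j]
    keep <- rows >= 1 & rows <= n
    ii <- rows[keep]
    jj <- grid$j[keep]
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, length(lag_samp)))
  attr(X, "lag_ms") <- lag_ms
  X
}

#' Ridge regression for TRF weights
#'
#' Solves `(X'X + lambda I) w = X'y` (standard ridge: identity penalty, no
#' intercept, no column scaling; impulse regressors share a common scale).
#' With `lambda = 0` and a singular normal matrix, the minimum-norm
#' pseudo-inverse solution is returned with a warning.
#'
#' @param design samples x lags matrix (dense or sparse).
#' @param response numeric vector, or samples x channels matrix for a
#'   shared-design multi-channel fit.
#' @param lambda ridge penalty (>= 0).
#' @return Weight vector (or lags x channels matrix), with `lag_ms`
#'   attribute propagated from the design.
#' @export
ridge_fit <- function(design, response, lambda) {
  stopifnot(lambda >= 0)
  y <- as.matrix(response)
  if (nrow(y) != nrow(design)) stop("design rows must equal response length")
  XtX <- as.matrix(Matrix::crossprod(design))
  Xty <- as.matrix(Matrix::crossprod(design, y))
  A <- XtX + diag(lambda, ncol(XtX))
  w <- tryCatch(solve(A, Xty), error = function(e) {
    warning("singular normal matrix; returning pseudo-inverse solution")
    MASS::ginv(A) %*% Xty
  })
  if (ncol(y) == 1 && is.null(colnames(response))) w <- drop(w)
  attr(w, "lag_ms") <- attr(design, "lag_ms")
  w
}

#' Predict the EEG response from a design and TRF weights
#'
#' @param design samples x lags matrix.
#' @param weights lag weight vector (or lags x channels matrix).
#' @return Predicted signal, `design %*% weights`.
#' @export
predict_response <- function(design, weights) {
  as.matrix(design %*% as.matrix(weights))
}

#' Mean squared error between actual and predicted responses
#'
#' @param actual,predicted numeric vectors/matrices of equal shape.
#' @return Mean of squared residuals (scalar).
#' @export
mse_score <- function(actual, predicted) {
  a <- as.matrix(actual)
  p <- as.matrix(predicted)
  stopifnot(all(dim(a) == dim(p)))
  mean((a - p)^2)
}

# Per-trial sufficient statistics for ridge fitting and MSE evaluation.
# From (XtX, XtY, ytY, n), both w(lambda) and the test MSE of arbitrary
# weights ( (y'y - 2 w'X'y + w'X'X w) / (n * n_channels) ) are exact,
# without keeping the raw signals.
.trial_suffstats <- function(design, response) {
  y <- as.matrix(response)
  XtX <- as.matrix(Matrix::crossprod(design))
  eig <- eigen(XtX, symmetric = TRUE)
  list(XtX = XtX, XtY = as.matrix(Matrix::crossprod(design, y)),
       ytY = colSums(y^2), n = nrow(y), V = eig$vectors, d = eig$values,
       lag_ms = attr(design, "lag_ms"))
}

.is_suffstats <- function(x) is.list(x) && !is.null(x$XtX) && !is.null(x$d)

.as_suffstats <- function(trial) {
  if (.is_suffstats(trial)) return(trial)
  .trial_suffstats(trial$design, trial$response)
}

# ridge weights from suffstats, all channels at once
.ridge_from_suffstats <- function(ss, lambda) {
  ss$V %*% ((t(ss$V) %*% ss$XtY) / (ss$d + lambda))
}

# exact mean squared error of weights w evaluated on a trial's suffstats
.mse_from_suffstats <- function(ss, w) {
  quad <- colSums(w * (ss$XtX %*% w))
  cross <- colSums(w * ss$XtY)
  mean((ss$ytY - 2 * cross + quad) / ss$n)
}

#' Select the ridge parameter by leave-one-trial-out cross-validation
#'
#' For each candidate lambda and each held-out trial: single-trial TRF
#' weights are estimated on every training trial, averaged, and the mean
#' squared error of the averaged weights is computed on the held-out trial
#' (averaged over channels). The lambda with the smallest MSE averaged over
#' held-out trials is returned; ties break toward the smaller lambda.
#'
#' @param trials list (length >= 2) of either `list(design=, response=)`
#'   pairs or precomputed sufficient statistics.
#' @param lambda_grid strictly increasing candidate penalties (default
#'   2^1..2^21).
#' @return List with `lambda` (selected value), `mse` (data frame lambda,
#'   mean_mse) and `per_trial` (held-out trial x lambda MSE matrix).
#' @export
loocv_lambda_select <- function(trials, lambda_grid = 2^(1:21)) {
  if (length(trials) < 2) {
    stop("leave-one-out lambda selection requires at least 2 trials")
  }
  stopifnot(length(lambda_grid) >= 1, !is.unsorted(lambda_grid, strictly = TRUE))
  ss <- lapply(trials, .as_suffstats)
  nt <- length(ss)
  # per-trial weights for every lambda: list [trial] of list [lambda]
  w_all <- lapply(ss, function(s) {
    proj <- t(s$V) %*% s$XtY
    lapply(lambda_grid, function(l) s$V %*% (proj / (s$d + l)))
  })
  per_trial <- matrix(NA_real_, nt, length(lambda_grid))
  for (j in seq_len(nt)) {
    train <- setdiff(seq_len(nt), j)
    for (li in seq_along(lambda_grid)) {
      wbar <- Reduce(`+`, lapply(train, function(i) w_all[[i]][[li]])) /
        length(train)
      per_trial[j, li] <- .mse_from_suffstats(ss[[j]], wbar)
    }
  }
  mean_mse <- colMeans(per_trial)
  best <- which(mean_mse <= min(mean_mse) + 0)
  sel <- lambda_grid[min(best)]
  list(lambda = sel,
       mse = data.frame(lambda = lambda_grid, mean_mse = mean_mse),
       per_trial = per_trial)
}

#' Population-level ridge parameter
#'
#' The most frequent value among per-subject selected parameters; ties
#' break toward the smaller value.
#'
#' @param lambdas numeric vector of per-subject selections.
#' @return The modal value.
#' @export
population_lambda <- function(lambdas) {
  stopifnot(length(lambdas) >= 1)
  tab <- table(lambdas)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

#' Estimate per-condition TRFs for one subject
#'
#' Single-trial ridge weights at the (population) regularisation parameter
#' are averaged by news condition, per channel.
#'
#' @param trials list of `list(design=, response=)` or sufficient
#'   statistics.
#' @param conditions character vector, one condition label per trial.
#' @param lambda ridge penalty.
#' @return A `trf_set`: array `[lag, channel, condition]` with attribute
#'   `lag_ms`.
#' @export
estimate_subject_trfs <- function(trials, conditions, lambda) {
  stopifnot(length(trials) == length(conditions))
  ss <- lapply(trials, .as_suffstats)
  conds <- unique(conditions)
  if (any(tabulate(factor(conditions, conds)) == 0)) {
    stop("every condition must have at least one trial")
  }
  w1 <- lapply(ss, .ridge_from_suffstats, lambda = lambda)
  n_ch <- ncol(w1[[1]])
  ch_names <- colnames(ss[[1]]$XtY)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(n_ch))
  lag_ms <- ss[[1]]$lag_ms
  out <- array(NA_real_, dim = c(nrow(w1[[1]]), n_ch, length(conds)),
               dimnames = list(NULL, ch_names, conds))
  for (cond in conds) {
    sel <- which(conditions == cond)
    out[, , cond] <- Reduce(`+`, w1[sel]) / length(sel)
  }
  attr(out, "lag_ms") <- lag_ms
  class(out) <- c("trf_set", class(out))
  out
}
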