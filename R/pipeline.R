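#' Run the full EEG analysis pipeline on a cohort
#'
#' Streams subject by subject to keep memory bounded: each subject's trials
#' are materialised (or taken from `cohort$trials` when present),
#' preprocessed, converted to lagged-design sufficient statistics, and the
#' raw signals discarded. The ridge parameter is selected per subject by
#' leave-one-trial-out cross-validation, the population parameter is the
#' mode across subjects, per-condition TRFs are estimated at that value,
#' component measures are extracted (fixed-window amplitudes, DTW-aligned
#' latencies) and the 18-column feature table is assembled.
#'
#' @param cohort a [generate_cohort()] / [read_cohort()] result.
#' @param preprocess a [preprocess_params()].
#' @param lag_range_ms TRF lag range in ms.
#' @param lambda_grid ridge candidate grid.
#' @param lambda fixed ridge parameter; skips per-subject selection when
#'   supplied (the per-subject LOOCV step is the default).
#' @param verbose print progress.
#' @return List of class `trf_pipeline`: `selected_lambdas` (per subject),
#'   `population_lambda`, `trf_sets` (per subject), `measures`, `features`,
#'   `config` echoes.
#' @export
run_trf_pipeline <- function(cohort, preprocess = preprocess_params(),
                             lag_range_ms = c(-100, 800),
                             lambda_grid = 2^(1:21), lambda = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  subjects <- cohort$subjects$subject_id
  fs_out <- preprocess$resample_to
  suff <- list()
  conds <- list()
  selected <- setNames(numeric(0), character(0))
  for (sid in subjects) {
    trs <- if (!is.null(cohort$trials)) {
      cohort$trials[[sid]]
    } else {
      generate_subject_trials(cohort, sid)
    }
    ss_subj <- vector("list", length(trs))
    cond_subj <- character(length(trs))
    for (k in seq_along(trs)) {
      tr <- preprocess_trial(trs[[k]], preprocess)
      n <- ncol(tr$signal)
      on <- cohort$onsets$onset_s[cohort$onsets$news_id == tr$news_id]
      stim <- build_stimulus_vector(on, fs_out, n)
      X <- build_lagged_design(stim, lag_range_ms, fs_out)
      ss_subj[[k]] <- .trial_suffstats(X, t(tr$signal))
      cond_subj[k] <- tr$condition
    }
    suff[[sid]] <- ss_subj
    conds[[sid]] <- cond_subj
    if (is.null(lambda)) {
      sel <- loocv_lambda_select(ss_subj, lambda_grid)
      selected[sid] <- sel$lambda
      if (verbose) message(sid, ": lambda = ", sel$lambda)
    }
  }
  pop_lambda <- if (is.null(lambda)) population_lambda(selected) else lambda
  trf_sets <- lapply(subjects, function(sid) {
    estimate_subject_trfs(suff[[sid]], conds[[sid]], pop_lambda)
  })
  names(trf_sets) <- subjects
  measures <- extract_component_measures(trf_sets)
  features <- build_feature_table(measures, cohort$ratings,
                                  cohort$subjects)
  structure(list(selected_lambdas = selected, population_lambda = pop_lambda,
                 trf_sets = trf_sets, measures = measures,
                 features = features,
                 lag_range_ms = lag_range_ms, lambda_grid = lambda_grid),
            class = "trf_pipeline")
}

#' Tidy long view of a set of subject TRFs
#'
#' @param trf_sets named list of `trf_set` arrays.
#' @return data.frame: subject_id, channel, condition, lag_ms, weight.
#' @export
trf_long <- function(trf_sets) {
  out <- do.call(rbind, lapply(names(trf_sets), function(sid) {
    ts <- trf_sets[[sid]]
    lag_ms <- attr(ts, "lag_ms")
    grid <- expand.grid(lag = seq_along(lag_ms),
                        channel = dimnames(ts)[[2]],
                        condition = dimnames(ts)[[3]],
                        stringsAsFactors = FALSE)
    data.frame(subject_id = sid, channel = grid$channel,
               condition = grid$condition, lag_ms = lag_ms[grid$lag],
               weight = ts[cbind(grid$lag, match(grid$channel, dimnames(ts)[[2]]),
                                 match(grid$condition, dimnames(ts)[[3]]))],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
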