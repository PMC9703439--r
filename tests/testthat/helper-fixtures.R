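# Shared fixtures. The pipeline fixture is expensive, so it is built once
# per test run, lazily, and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# A compact, strongly separated cohort pushed through the full pipeline:
# 6 depressed / 14 non-depressed, short trials at 200 Hz, effect_scale 3,
# low noise. Large enough that a random label permutation essentially never
# reproduces the group split. Used by the feature-plumbing and permutation
# tests.
separated_pipeline_fixture <- function() {
  if (is.null(.fixture_env$sep)) {
    cfg <- cohort_config(n_depressed = 6, n_nondepressed = 14,
                         trial_duration_s = c(20, 26), fs_hz = 200,
                         snr_db = 0, effect_scale = 3, seed = 101)
    cohort <- generate_cohort(cfg)
    pipe <- run_trf_pipeline(cohort, lambda_grid = 2^seq(1, 21, by = 4))
    .fixture_env$sep <- list(cohort = cohort, pipe = pipe)
  }
  .fixture_env$sep
}

# Sufficient statistics for one synthetic subject's trials at a given SNR,
# bypassing nothing: generation -> preprocessing -> design -> suffstats.
subject_suffstats <- function(cohort, subject_id,
                              params = preprocess_params()) {
  trs <- generate_subject_trials(cohort, subject_id)
  lapply(trs, function(tr) {
    sig <- preprocess_trial(tr, params)$signal
    on <- cohort$onsets$onset_s[cohort$onsets$news_id == tr$news_id]
    stim <- build_stimulus_vector(on, params$resample_to, ncol(sig))
    X <- build_lagged_design(stim, c(-100, 800), params$resample_to)
    moodtrf:::.trial_suffstats(X, t(sig))
  })
}

# Fully null factorial table at the rating level: every cell drawn from the
# same (neutral-condition, effect-free) rating distribution so that Group,
# News and the interaction are all truly null.
null_rating_table <- function(n_per_group = 8, plan = effect_plan()) {
  groups <- rep(c("depressed", "non-depressed"), each = n_per_group)
  conds <- c("negative", "neutral", "positive")
  do.call(rbind, lapply(seq_along(groups), function(i) {
    vals <- vapply(conds, function(cd) {
      mean(generate_ratings(groups[i], "neutral", plan, n = 5,
                            effect_scale = 0)$arousal)
    }, 0)
    data.frame(subject = sprintf("s%02d", i), group = groups[i],
               news = conds, value = vals, stringsAsFactors = FALSE)
  }))
}
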