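#' Write a cohort to disk
#'
#' Directory layout (all plain text, UTF-8, "." decimal separator):
#' \describe{
#'   \item{subjects.csv}{subject_id, group, bdi_score}
#'   \item{news.csv}{news_id, condition, duration_s}
#'   \item{onsets.tsv}{news_id, onset_s, token}
#'   \item{ratings.csv}{subject_id, news_id, condition, valence, arousal,
#'     interest, comprehensibility}
#'   \item{ground_truth.json}{injected kernel parameters and rating means}
#'   \item{eeg/<subject>/<news_id>.csv}{one column per channel (Fpz, Cz,
#'     Pz), one row per sample}
#'   \item{eeg/<subject>/meta.json}{fs_hz plus per-trial news_id, condition
#'     and duration}
#' }
#' Times are stored in seconds, trial-relative; sample indexing is 0-based
#' in all documentation (sample k covers time k / fs).
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output directory.
#' @param overwrite logical; refuse to write into an existing directory
#'   unless `TRUE`.
#' @param trials optional pre-materialised trials (named list by subject of
#'   named lists by news_id); when `NULL`, each subject's EEG is generated
#'   on the fly with [generate_subject_trials()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, overwrite = FALSE, trials = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (dir.exists(path) && length(dir(path)) > 0 && !overwrite) {
    stop("output path exists and is non-empty; use overwrite = TRUE: ", path)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$subjects, file.path(path, "subjects.csv"))
  data.table::fwrite(cohort$news, file.path(path, "news.csv"))
  data.table::fwrite(cohort$onsets, file.path(path, "onsets.tsv"), sep = "\t")
  data.table::fwrite(cohort$ratings, file.path(path, "ratings.csv"))
  jsonlite::write_json(
    list(params = cohort$ground_truth$params,
         rating_means = as.data.frame(cohort$ground_truth$rating_means),
         config = unclass(cohort$config), plan = unclass(cohort$plan)),
    file.path(path, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  for (sid in cohort$subjects$subject_id) {
    sdir <- file.path(path, "eeg", sid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    trs <- if (is.null(trials)) generate_subject_trials(cohort, sid) else trials[[sid]]
    meta <- list(subject_id = sid, fs_hz = cohort$config$fs_hz,
                 trials = lapply(unname(trs), function(tr) {
                   list(news_id = tr$news_id, condition = tr$condition,
                        duration_s = tr$duration_s)
                 }))
    jsonlite::write_json(meta, file.path(sdir, "meta.json"),
                         digits = NA, auto_unbox = TRUE)
    for (tr in trs) {
      data.table::fwrite(as.data.frame(t(tr$signal)),
                         file.path(sdir, paste0(tr$news_id, ".csv")))
    }
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' Validates the schema while reading: every EEG file must contain the
#' channels Fpz, Cz and Pz, every trial must reference a known subject and
#' news item, and every word onset must fall inside its trial.
#'
#' @param path directory written by [write_cohort()].
#' @param load_eeg logical; read the (possibly large) EEG arrays too.
#' @return A `cohort` object; when `load_eeg = TRUE` it additionally carries
#'   `$trials`, a named list (by subject) of named lists (by news_id) of
#'   `trial_recording` objects.
#' @export
read_cohort <- function(path, load_eeg = TRUE) {
  if (!dir.exists(path)) stop("no such cohort directory: ", path)
  subjects <- as.data.frame(data.table::fread(file.path(path, "subjects.csv")))
  news <- as.data.frame(data.table::fread(file.path(path, "news.csv")))
  onsets <- as.data.frame(data.table::fread(file.path(path, "onsets.tsv")))
  ratings <- as.data.frame(data.table::fread(file.path(path, "ratings.csv")))
  gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                            simplifyVector = TRUE)
  dur <- news$duration_s[match(onsets$news_id, news$news_id)]
  bad <- is.na(dur) | onsets$onset_s < 0 | onsets$onset_s >= dur
  if (any(bad)) {
    stop(sprintf("validation error: %d onset(s) outside their trial (first: %s at %.3f s)",
                 sum(bad), onsets$news_id[which(bad)[1]],
                 onsets$onset_s[which(bad)[1]]))
  }
  cfg <- do.call(cohort_config, gt$config)
  plan <- do.call(effect_plan, gt$plan)
  cohort <- structure(
    list(config = cfg, plan = plan, news = news, onsets = onsets,
         subjects = subjects, ratings = ratings,
         ground_truth = list(params = gt$params,
                             rating_means = as.matrix(gt$rating_means))),
    class = "cohort")
  if (load_eeg) {
    cohort$trials <- setNames(lapply(subjects$subject_id, function(sid) {
      sdir <- file.path(path, "eeg", sid)
      meta <- jsonlite::read_json(file.path(sdir, "meta.json"),
                                  simplifyVector = TRUE)
      trs <- lapply(seq_len(nrow(meta$trials)), function(j) {
        nid <- meta$trials$news_id[j]
        df <- data.table::fread(file.path(sdir, paste0(nid, ".csv")))
        missing <- setdiff(c("Fpz", "Cz", "Pz"), names(df))
        if (length(missing)) {
          stop("schema error: EEG trial ", sid, "/", nid,
               " is missing channel(s): ", paste(missing, collapse = ", "))
        }
        sig <- t(as.matrix(df[, c("Fpz", "Cz", "Pz")]))
        structure(list(signal = sig, fs_hz = meta$fs_hz,
                       duration_s = meta$trials$duration_s[j],
                       news_id = nid, condition = meta$trials$condition[j],
                       subject_id = sid), class = "trial_recording")
      })
      names(trs) <- meta$trials$news_id
      trs
    }), subjects$subject_id)
  }
  cohort
}

#' Default analysis configuration
#'
#' Every default reproduces the published analysis settings: 1-50 Hz
#' (order 3300) then 1-8 Hz (order 1320) zero-phase FIR band-passes,
#' resampling to 200 Hz, TRF lags -100..800 ms, a regularisation grid of
#' 2^1..2^21, component windows 100-160 / 170-230 / 300-600 ms, a cost grid
#' of 10^-3..10^3, three stratified inner folds and 1000 label permutations.
#'
#' @return Named list of parameter groups.
#' @export
default_pipeline_config <- function() {
  list(
    preprocess = list(bp1 = c(1, 50), bp1_order = 3300, resample_to = 200,
                      bp2 = c(1, 8), bp2_order = 1320,
                      artifact_threshold_uv = 500),
    trf = list(lag_range_ms = c(-100, 800), lambda_grid = 2^(1:21)),
    components = list(windows = list(N1 = c(100, 160), P2 = c(170, 230),
                                     N400 = c(300, 600))),
    classifier = list(feature_set = "combination", n_selected = 6,
                      C_grid = 10^(-3:3), inner_folds = 3,
                      n_permutations = 1000),
    seed = 1L
  )
}

#' Load an analysis configuration from YAML
#'
#' Starts from [default_pipeline_config()] and merges the file contents and
#' then `overrides` on top. Unknown keys (at the group or parameter level)
#' are rejected.
#'
#' @param path YAML file; `NULL` or an empty file yields the defaults.
#' @param overrides named list merged last.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  merge_checked <- function(base, new, where) {
    if (is.null(new)) return(base)
    unknown <- setdiff(names(new), names(base))
    if (length(unknown)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
    for (k in names(new)) {
      if (is.list(base[[k]]) && is.list(new[[k]]) &&
          !is.null(names(base[[k]]))) {
        base[[k]] <- merge_checked(base[[k]], new[[k]],
                                   paste0(where, "$", k))
      } else {
        base[[k]] <- new[[k]]
      }
    }
    base
  }
  if (!is.null(path)) {
    parsed <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("config parse error in ", path, ": ", conditionMessage(e))
    })
    cfg <- merge_checked(cfg, parsed, "config")
  }
  cfg <- merge_checked(cfg, overrides, "overrides")
  if (length(cfg$trf$lambda_grid) == 0) {
    stop("config error: lambda_grid must be non-empty")
  }
  cfg
}
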