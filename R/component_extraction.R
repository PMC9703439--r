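#' Component measurement windows
#'
#' N1: 100-160 ms (negative), P2: 170-230 ms (positive), N400: 300-600 ms
#' (negative). Window endpoints are inclusive on the lag grid.
#'
#' @return data.frame with columns component, lo_ms, hi_ms, polarity.
#' @export
component_windows <- function() {
  data.frame(component = c("N1", "P2", "N400"),
             lo_ms = c(100, 170, 300), hi_ms = c(160, 230, 600),
             polarity = c(-1, 1, -1), stringsAsFactors = FALSE)
}

#' Mean amplitude of a TRF inside a component window
#'
#' Arithmetic mean of the weights at lag samples inside `[lo_ms, hi_ms]`
#' (inclusive).
#'
#' @param weights numeric TRF weight vector.
#' @param lag_ms lag axis in ms (same length); taken from the `lag_ms`
#'   attribute when omitted.
#' @param window length-2 numeric `c(lo_ms, hi_ms)`.
#' @return Scalar mean amplitude.
#' @export
window_mean_amplitude <- function(weights, window, lag_ms = NULL) {
  if (is.null(lag_ms)) lag_ms <- attr(weights, "lag_ms")
  stopifnot(length(lag_ms) == length(weights))
  sel <- lag_ms >= window[1] & lag_ms <= window[2]
  if (!any(sel)) stop("window contains no lag samples")
  mean(weights[sel])
}

#' Grand-average TRF across subjects
#'
#' Pointwise mean with equal subject weighting.
#'
#' @param trf_list list of numeric weight vectors (equal length), or a
#'   subjects x lags matrix.
#' @return Numeric mean curve.
#' @export
grand_average_trf <- function(trf_list) {
  m <- if (is.matrix(trf_list)) trf_list else do.call(rbind, trf_list)
  colMeans(m)
}

#' Detect the component peak on a grand-average TRF
#'
#' Polarity-appropriate extremum (minimum for negative components, maximum
#' for positive) inside the component window; ties resolve to the earliest
#' lag. A flat window returns its earliest lag with a warning.
#'
#' @param weights grand-average weight vector.
#' @param window length-2 `c(lo_ms, hi_ms)`.
#' @param polarity -1 or +1.
#' @param lag_ms lag axis; taken from the attribute when omitted.
#' @return Peak latency in ms.
#' @export
detect_ga_peak <- function(weights, window, polarity, lag_ms = NULL) {
  if (is.null(lag_ms)) lag_ms <- attr(weights, "lag_ms")
  sel <- which(lag_ms >= window[1] & lag_ms <= window[2])
  if (!length(sel)) stop("window contains no lag samples")
  w <- weights[sel] * polarity          # maximise regardless of polarity
  if (diff(range(w)) == 0) {
    warning("flat TRF inside component window; returning earliest lag")
    return(lag_ms[sel[1]])
  }
  lag_ms[sel[which.max(w)]]
}

#' Dynamic time warping between two series
#'
#' Absolute-difference local cost, symmetric unit steps
#' \{(1,1), (1,0), (0,1)\}, no warping-window constraint. The returned path
#' starts at (1, 1), ends at (n, m), and is monotone with unit steps; the
#' cost is the minimal summed local cost over all such paths.
#'
#' @param a,b numeric series of length >= 2.
#' @return List with `path` (two-column index matrix) and `cost`.
#' @export
dtw_warp <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both series must have length >= 2")
  }
  cpp_dtw(as.numeric(a), as.numeric(b))
}

#' Per-subject component peak latency via DTW alignment
#'
#' Both curves are z-scored (amplitude-invariant alignment), the subject
#' TRF is warped onto the grand average, and the subject lag samples
#' aligned to the grand-average peak sample are collected; the mean of
#' their lags is the subject's peak latency.
#'
#' @param subject_weights,ga_weights TRF weight vectors on a common lag
#'   grid.
#' @param ga_peak_ms grand-average peak latency (from [detect_ga_peak()]).
#' @param lag_ms lag axis.
#' @return Subject peak latency in ms.
#' @export
subject_peak_latency <- function(subject_weights, ga_weights, ga_peak_ms,
                                 lag_ms = NULL) {
  if (is.null(lag_ms)) lag_ms <- attr(ga_weights, "lag_ms")
  stopifnot(length(subject_weights) == length(ga_weights),
            length(lag_ms) == length(ga_weights))
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x - mean(x)
  wp <- dtw_warp(zs(subject_weights), zs(ga_weights))
  peak_j <- which.min(abs(lag_ms - ga_peak_ms))
  ii <- wp$path[wp$path[, 2] == peak_j, 1]
  mean(lag_ms[ii])
}

#' Extract component measures for every subject
#'
#' For each channel x condition: grand-average TRFs are computed across
#' subjects, component peaks are detected on the grand average inside each
#' component's amplitude window, and every subject receives a fixed-window
#' mean amplitude plus a DTW-aligned peak latency per component.
#'
#' @param trf_sets named list (by subject) of `trf_set` arrays from
#'   [estimate_subject_trfs()], sharing dimensions.
#' @param windows component window table (default [component_windows()]).
#' @return data.frame: subject_id, channel, condition, component,
#'   mean_amplitude, peak_latency_ms.
#' @export
extract_component_measures <- function(trf_sets,
                                       windows = component_windows()) {
  stopifnot(length(trf_sets) >= 1)
  first <- trf_sets[[1]]
  channels <- dimnames(first)[[2]]
  conditions <- dimnames(first)[[3]]
  lag_ms <- attr(first, "lag_ms")
  subjects <- names(trf_sets)
  out <- list()
  for (ch in channels) {
    for (cond in conditions) {
      mat <- do.call(rbind, lapply(trf_sets, function(ts) ts[, ch, cond]))
      ga <- grand_average_trf(mat)
      for (k in seq_len(nrow(windows))) {
        win <- c(windows$lo_ms[k], windows$hi_ms[k])
        ga_peak <- detect_ga_peak(ga, win, windows$polarity[k], lag_ms)
        amp <- apply(mat, 1, window_mean_amplitude, window = win,
                     lag_ms = lag_ms)
        lat <- apply(mat, 1, subject_peak_latency, ga_weights = ga,
                     ga_peak_ms = ga_peak, lag_ms = lag_ms)
        out[[length(out) + 1]] <- data.frame(
          subject_id = subjects, channel = ch, condition = cond,
          component = windows$component[k], mean_amplitude = unname(amp),
          peak_latency_ms = unname(lat), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# canonical feature column names
.eeg_feature_names <- function() {
  conds <- c("negative", "neutral", "positive")
  c(paste0("N1_latency_Fpz_", conds), paste0("P2_latency_Fpz_", conds),
    paste0("N1_amplitude_Pz_", conds), paste0("N400_amplitude_Pz_", conds))
}

.rating_feature_names <- function() {
  conds <- c("negative", "neutral", "positive")
  c(paste0("arousal_", conds), paste0("comprehensibility_", conds))
}

#' Feature columns of a feature set
#'
#' @param feature_set `"eeg_only"` (12 features), `"subjective_only"` (6)
#'   or `"combination"` (18).
#' @return Character vector of column names.
#' @export
feature_columns <- function(feature_set = c("combination", "eeg_only",
                                            "subjective_only")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
         eeg_only = .eeg_feature_names(),
         subjective_only = .rating_feature_names(),
         combination = c(.eeg_feature_names(), .rating_feature_names()))
}

#' Assemble the per-subject feature table
#'
#' 12 EEG features (N1 and P2 peak latencies at Fpz; N1 and N400 mean
#' amplitudes at Pz; each per news condition) plus 6 subjective features
#' (per-condition mean arousal and comprehensibility over the subject's
#' trials), with the group label.
#'
#' @param measures component measure table from
#'   [extract_component_measures()].
#' @param ratings long rating table (subject_id, condition, arousal,
#'   comprehensibility, one row per trial).
#' @param labels data.frame subject_id, group.
#' @return data.frame: subject_id, group, then the 18 feature columns.
#' @export
build_feature_table <- function(measures, ratings, labels) {
  conds <- c("negative", "neutral", "positive")
  subjects <- labels$subject_id
  pick <- function(sid, comp, ch, cond, what) {
    v <- measures[measures$subject_id == sid & measures$component == comp &
                    measures$channel == ch & measures$condition == cond,
                  what]
    if (length(v) != 1 || is.na(v)) {
      stop(sprintf("missing component measure: subject %s, %s %s at %s",
                   sid, cond, comp, ch))
    }
    v
  }
  rows <- lapply(subjects, function(sid) {
    vals <- c(
      vapply(conds, function(cd) pick(sid, "N1", "Fpz", cd,
                                      "peak_latency_ms"), 0),
      vapply(conds, function(cd) pick(sid, "P2", "Fpz", cd,
                                      "peak_latency_ms"), 0),
      vapply(conds, function(cd) pick(sid, "N1", "Pz", cd,
                                      "mean_amplitude"), 0),
      vapply(conds, function(cd) pick(sid, "N400", "Pz", cd,
                                      "mean_amplitude"), 0))
    rat <- vapply(conds, function(cd) {
      sel <- ratings$subject_id == sid & ratings$condition == cd
      if (!any(sel)) {
        stop(sprintf("missing ratings: subject %s, condition %s", sid, cd))
      }
      c(mean(ratings$arousal[sel], na.rm = TRUE),
        mean(ratings$comprehensibility[sel], na.rm = TRUE))
    }, numeric(2))
    c(vals, rat[1, ], rat[2, ])
  })
  ft <- as.data.frame(do.call(rbind, rows))
  names(ft) <- c(.eeg_feature_names(), .rating_feature_names())
  if (anyNA(ft)) {
    bad <- which(is.na(ft), arr.ind = TRUE)
    stop("missing feature value: subject ", subjects[bad[1, 1]],
         ", feature ", names(ft)[bad[1, 2]])
  }
  cbind(data.frame(subject_id = subjects, group = labels$group,
                   stringsAsFactors = FALSE), ft)
}
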