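#' Cohort generation configuration
#'
#' Holds the design of a synthetic listening cohort. Defaults reproduce the
#' study conditions: 32 depressed / 103 non-depressed subjects, five news
#' items per affective condition, trial (news item) durations drawn uniformly
#' between 45 and 83 s, EEG sampled at 500 Hz, and a content-word rate of
#' 2.5 words/s (a plausible broadcast-speech value; configurable, not a
#' measured quantity).
#'
#' @param n_depressed,n_nondepressed number of subjects per group.
#' @param n_trials_per_condition news items per affective condition.
#' @param trial_duration_s length-2 numeric; uniform range of news item
#'   durations in seconds.
#' @param fs_hz EEG sampling rate in Hz (>= 200).
#' @param word_rate_hz mean content-word rate in words/s.
#' @param snr_db signal-to-noise ratio (dB) of the kernel train relative to
#'   the 1/f background, per channel.
#' @param effect_scale multiplier applied to every group/news effect in the
#'   [effect_plan()]; 0 gives a null cohort.
#' @param seed integer seed; the cohort (including per-subject EEG) is a
#'   deterministic function of the configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_depressed = 32L, n_nondepressed = 103L,
                          n_trials_per_condition = 5L,
                          trial_duration_s = c(45, 83), fs_hz = 500,
                          word_rate_hz = 2.5, snr_db = -10,
                          effect_scale = 1, seed = 1L) {
  stopifnot(n_depressed > 0, n_nondepressed > 0, n_trials_per_condition > 0)
  if (fs_hz < 200) stop("fs_hz must be >= 200 Hz")
  if (effect_scale < 0) stop("effect_scale must be >= 0")
  if (length(trial_duration_s) == 1L) {
    trial_duration_s <- rep(trial_duration_s, 2L)
  }
  stopifnot(length(trial_duration_s) == 2L,
            trial_duration_s[1] <= trial_duration_s[2],
            trial_duration_s[1] > 0, word_rate_hz > 0)
  structure(list(n_depressed = as.integer(n_depressed),
                 n_nondepressed = as.integer(n_nondepressed),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 trial_duration_s = as.numeric(trial_duration_s),
                 fs_hz = as.numeric(fs_hz),
                 word_rate_hz = as.numeric(word_rate_hz),
                 snr_db = as.numeric(snr_db),
                 effect_scale = as.numeric(effect_scale),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Group-by-news effect plan
#'
#' Magnitudes of the effects injected into synthetic cohorts, on the scale
#' reported for the real cohort: depressed listeners show N1/P2 peak
#' latencies 21/27 ms longer for positive news; the N400 peak for negative
#' news leads the positive-news peak by 33.3 ms in both groups; the N400
#' deflection to negative news is deeper in the depressed group; the N1
#' deflection is deeper in non-depressed listeners; depressed listeners rate
#' arousal and comprehensibility lower.
#'
#' @param n1_latency_shift_positive_ms,p2_latency_shift_positive_ms latency
#'   shifts (ms) added for depressed subjects listening to positive news.
#' @param n400_latency_negative_vs_positive_ms N400 latency for negative
#'   minus positive news (ms, both groups); applied as a symmetric shift
#'   around the neutral-news peak.
#' @param n400_amp_gain_negative_depressed,n1_amp_gain_nondepressed
#'   multiplicative amplitude gains (> 1).
#' @param arousal_shift_depressed,comprehensibility_shift_depressed additive
#'   shifts (rating points, negative) on the latent rating means of the
#'   depressed group.
#' @return An object of class `effect_plan`.
#' @export
effect_plan <- function(n1_latency_shift_positive_ms = 21,
                        p2_latency_shift_positive_ms = 27,
                        n400_latency_negative_vs_positive_ms = -33.3,
                        n400_amp_gain_negative_depressed = 1.3,
                        n1_amp_gain_nondepressed = 1.25,
                        arousal_shift_depressed = -0.4,
                        comprehensibility_shift_depressed = -0.5) {
  stopifnot(n400_amp_gain_negative_depressed >= 1,
            n1_amp_gain_nondepressed >= 1)
  structure(list(
    n1_latency_shift_positive_ms = n1_latency_shift_positive_ms,
    p2_latency_shift_positive_ms = p2_latency_shift_positive_ms,
    n400_latency_negative_vs_positive_ms = n400_latency_negative_vs_positive_ms,
    n400_amp_gain_negative_depressed = n400_amp_gain_negative_depressed,
    n1_amp_gain_nondepressed = n1_amp_gain_nondepressed,
    arousal_shift_depressed = arousal_shift_depressed,
    comprehensibility_shift_depressed = comprehensibility_shift_depressed),
    class = "effect_plan")
}

#' Component kernel specification
#'
#' A Gaussian bump standing in for one event-related component on the TRF lag
#' axis. Polarity must match the sign of `amplitude`.
#'
#' @param name one of `"N1"`, `"P2"`, `"N400"`.
#' @param polarity `"negative"` or `"positive"`.
#' @param peak_latency_ms peak location in \[0, 800\] ms.
#' @param amplitude peak amplitude (arbitrary units, sign = polarity).
#' @param width_ms full width at half maximum in ms (> 0).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(name, polarity, peak_latency_ms, amplitude, width_ms) {
  name <- match.arg(name, c("N1", "P2", "N400"))
  polarity <- match.arg(polarity, c("negative", "positive"))
  if (width_ms <= 0) stop("invalid kernel spec: width_ms must be > 0")
  if (peak_latency_ms < 0 || peak_latency_ms > 800) {
    stop("invalid kernel spec: peak_latency_ms must lie in [0, 800] ms")
  }
  if (amplitude != 0) {
    if (polarity == "negative" && amplitude > 0 ||
        polarity == "positive" && amplitude < 0) {
      stop("invalid kernel spec: amplitude sign does not match polarity")
    }
  }
  structure(list(name = name, polarity = polarity,
                 peak_latency_ms = peak_latency_ms, amplitude = amplitude,
                 width_ms = width_ms), class = "kernel_spec")
}

#' Baseline kernel specifications for N1, P2 and N400
#'
#' N1: negative, peak 130 ms, FWHM 40 ms; P2: positive, peak 200 ms, FWHM
#' 50 ms; N400: negative, peak 420 ms, FWHM 180 ms. All peaks fall inside
#' the component measurement windows (100-160, 170-230, 300-600 ms).
#'
#' @return Named list of [kernel_spec()] objects.
#' @export
default_kernel_specs <- function() {
  list(N1 = kernel_spec("N1", "negative", 130, -1.0, 40),
       P2 = kernel_spec("P2", "positive", 200, 1.2, 50),
       N400 = kernel_spec("N400", "negative", 420, -1.5, 180))
}

#' Channel mixing matrix for the three-component kernel model
#'
#' Rows are channels, columns components. N1/P2 dominate at Fpz, N400 at Pz,
#' and all components are present at Cz, mirroring the fronto-central versus
#' centro-parietal scalp distributions of auditory N1/P2 and N400.
#'
#' @return 3 x 3 numeric matrix with dimnames.
#' @export
default_channel_mix <- function() {
  m <- rbind(Fpz = c(1.0, 1.0, 0.4),
             Cz  = c(0.8, 0.8, 0.8),
             Pz  = c(0.6, 0.5, 1.0))
  colnames(m) <- c("N1", "P2", "N400")
  m
}

#' Generate content-word onset times for one news item
#'
#' Jittered renewal process: inter-onset gaps are 150 ms (an articulatory
#' floor) plus an exponential draw whose mean keeps the overall rate at
#' `word_rate_hz`. Onsets are confined to \[0.5, duration - 1\] s so that
#' every word response fits inside the trial.
#'
#' @param duration_s trial duration in seconds (> 0).
#' @param word_rate_hz mean content-word rate (words/s).
#' @param min_gap_s minimum inter-onset gap in seconds.
#' @return Strictly increasing numeric vector of onset times (seconds);
#'   empty (with a warning) when the trial is too short to place one onset.
#' @export
generate_word_onsets <- function(duration_s, word_rate_hz = 2.5,
                                 min_gap_s = 0.15) {
  stopifnot(duration_s > 0, word_rate_hz > 0)
  lo <- 0.5
  hi <- duration_s - 1
  if (hi < lo) {
    warning("trial too short to place any word onset; returning empty list")
    return(numeric(0))
  }
  mean_gap <- 1 / word_rate_hz
  exp_mean <- max(mean_gap - min_gap_s, 1e-3)
  onsets <- numeric(0)
  t <- lo
  repeat {
    if (t > hi) break
    onsets <- c(onsets, t)
    t <- t + min_gap_s + rexp(1, rate = 1 / exp_mean)
  }
  onsets
}

#' Sample a component kernel on the 0..800 ms lag grid
#'
#' @param spec a [kernel_spec()].
#' @param fs_hz sampling rate (>= 200 Hz).
#' @return Numeric vector over lags 0..800 ms inclusive, with attribute
#'   `lag_ms`.
#' @export
component_kernel <- function(spec, fs_hz) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (fs_hz < 200) stop("fs_hz must be >= 200 Hz")
  lag_ms <- seq(0, 800, by = 1000 / fs_hz)
  sigma <- spec$width_ms / (2 * sqrt(2 * log(2)))
  k <- spec$amplitude * exp(-((lag_ms - spec$peak_latency_ms)^2) /
                              (2 * sigma^2))
  attr(k, "lag_ms") <- lag_ms
  k
}

#' Band-limited 1/f (pink) noise
#'
#' Spectral-shaping construction: complex Gaussian spectrum with amplitude
#' proportional to f^(-1/2) inside `band` and zero outside, inverse
#' transformed to a real series and scaled to unit variance.
#'
#' @param n number of samples.
#' @param fs_hz sampling rate.
#' @param band length-2 passband in Hz (default 1-50, the EEG analysis band).
#' @return Numeric vector of length `n` with (approximately) unit variance.
#' @export
pink_noise <- function(n, fs_hz, band = c(1, 50)) {
  stopifnot(n > 1)
  freqs <- (0:(n - 1)) * fs_hz / n
  freqs[freqs > fs_hz / 2] <- fs_hz - freqs[freqs > fs_hz / 2]
  amp <- ifelse(freqs >= band[1] & freqs <= band[2], 1 / sqrt(pmax(freqs, 1e-12)), 0)
  half <- floor(n / 2)
  phase <- complex(modulus = 1, argument = runif(n, -pi, pi))
  spec <- amp * phase
  # enforce Hermitian symmetry for a real output
  spec[1] <- 0
  if (n %% 2 == 0) spec[half + 1] <- Re(spec[half + 1])
  if (half >= 2) spec[n:(n - half + 2)] <- Conj(spec[2:half])
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

#' Synthesize one EEG trial from word onsets and component kernels
#'
#' The clean signal at each channel is the sum over onsets of the
#' channel-mixed kernels placed at the onset sample (the generative inverse
#' of the TRF model), to which band-limited 1/f noise is added at the
#' requested signal-to-noise ratio.
#'
#' @param onsets onset times in seconds; all must lie within the trial.
#' @param kernels named list of kernel vectors (`N1`, `P2`, `N400`) sampled
#'   at `fs_hz` (see [component_kernel()]).
#' @param fs_hz sampling rate.
#' @param duration_s trial duration in seconds.
#' @param snr_db kernel-train-power to noise-power ratio in dB; `Inf`
#'   disables noise.
#' @param channel_mix channels x components mixing matrix
#'   (default [default_channel_mix()]).
#' @return A `trial_recording`: list with `signal` (channels x samples
#'   matrix, rows Fpz/Cz/Pz), `fs_hz`, `duration_s`.
#' @export
synthesize_trial <- function(onsets, kernels, fs_hz, duration_s,
                             snr_db = -10, channel_mix = default_channel_mix()) {
  n <- round(duration_s * fs_hz)
  bad <- onsets < 0 | onsets >= duration_s
  if (any(bad)) {
    stop(sprintf("onset(s) outside trial duration: %s",
                 paste(format(onsets[bad]), collapse = ", ")))
  }
  stopifnot(all(c("N1", "P2", "N400") %in% names(kernels)))
  channels <- rownames(channel_mix)
  sig <- matrix(0, nrow = nrow(channel_mix), ncol = n,
                dimnames = list(channels, NULL))
  idx <- round(onsets * fs_hz) + 1L
  for (ch in seq_along(channels)) {
    kc <- channel_mix[ch, "N1"] * kernels$N1 +
      channel_mix[ch, "P2"] * kernels$P2 +
      channel_mix[ch, "N400"] * kernels$N400
    lk <- length(kc)
    for (i in idx) {
      j <- i:min(i + lk - 1L, n)
      sig[ch, j] <- sig[ch, j] + kc[seq_along(j)]
    }
  }
  if (is.finite(snr_db)) {
    for (ch in seq_len(nrow(sig))) {
      noise <- pink_noise(n, fs_hz)
      p_sig <- mean(sig[ch, ]^2)
      p_target <- if (p_sig > 0) p_sig / 10^(snr_db / 10) else 1
      sig[ch, ] <- sig[ch, ] + noise * sqrt(p_target / mean(noise^2))
    }
  }
  structure(list(signal = sig, fs_hz = fs_hz, duration_s = duration_s),
            class = "trial_recording")
}

# latent rating means per (item, condition); values follow the published
# preliminary-survey means (5-point scales)
.rating_means <- function() {
  rbind(valence = c(negative = 1.8, neutral = 3.2, positive = 3.9),
        arousal = c(negative = 3.1, neutral = 2.8, positive = 3.0),
        interest = c(negative = 3.1, neutral = 2.7, positive = 2.8),
        comprehensibility = c(negative = 3.7, neutral = 3.4, positive = 3.9))
}

#' Generate subjective ratings for one group x condition cell
#'
#' Latent Gaussian model: each of the four 5-point items (valence, arousal,
#' interest, comprehensibility) is drawn from a normal with
#' condition-specific mean (group shifts on arousal and comprehensibility
#' for the depressed group), rounded and clamped to 1..5.
#'
#' @param group `"depressed"` or `"non-depressed"`.
#' @param condition `"negative"`, `"neutral"` or `"positive"`.
#' @param plan an [effect_plan()].
#' @param n number of rating rows to draw.
#' @param effect_scale multiplier on the group shifts.
#' @param latent_sd latent standard deviation (rating points).
#' @return data.frame with integer columns valence, arousal, interest,
#'   comprehensibility in 1..5.
#' @export
generate_ratings <- function(group, condition, plan = effect_plan(), n = 1,
                             effect_scale = 1, latent_sd = 0.7) {
  group <- match.arg(group, c("depressed", "non-depressed"))
  condition <- match.arg(condition, c("negative", "neutral", "positive"))
  mu <- .rating_means()[, condition]
  if (group == "depressed") {
    mu["arousal"] <- mu["arousal"] + plan$arousal_shift_depressed * effect_scale
    mu["comprehensibility"] <- mu["comprehensibility"] +
      plan$comprehensibility_shift_depressed * effect_scale
  }
  out <- vapply(names(mu), function(item) {
    pmin(pmax(round(rnorm(n, mu[item], latent_sd)), 1), 5)
  }, numeric(n))
  out <- matrix(as.integer(out), nrow = n,
                dimnames = list(NULL, names(mu)))
  as.data.frame(out)
}

# injected kernel parameters (latency/amplitude) for one group x condition
.kernel_params <- function(group, condition, plan, effect_scale,
                           base = default_kernel_specs()) {
  s <- effect_scale
  n1_lat <- base$N1$peak_latency_ms
  p2_lat <- base$P2$peak_latency_ms
  n400_lat <- base$N400$peak_latency_ms
  n1_amp <- base$N1$amplitude
  p2_amp <- base$P2$amplitude
  n400_amp <- base$N400$amplitude
  if (group == "depressed" && condition == "positive") {
    n1_lat <- n1_lat + plan$n1_latency_shift_positive_ms * s
    p2_lat <- p2_lat + plan$p2_latency_shift_positive_ms * s
  }
  half <- plan$n400_latency_negative_vs_positive_ms / 2
  if (condition == "negative") n400_lat <- n400_lat + half * s
  if (condition == "positive") n400_lat <- n400_lat - half * s
  if (group == "non-depressed") {
    n1_amp <- n1_amp * (1 + (plan$n1_amp_gain_nondepressed - 1) * s)
  }
  if (group == "depressed" && condition == "negative") {
    n400_amp <- n400_amp * (1 + (plan$n400_amp_gain_negative_depressed - 1) * s)
  }
  list(N1 = kernel_spec("N1", "negative", n1_lat, n1_amp, base$N1$width_ms),
       P2 = kernel_spec("P2", "positive", p2_lat, p2_amp, base$P2$width_ms),
       N400 = kernel_spec("N400", "negative", n400_lat, n400_amp,
                          base$N400$width_ms))
}

# deterministic per-subject RNG substream
.subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 7919 + subject_index * 104729) %% 2147483647)
}

#' Generate a synthetic listening cohort
#'
#' Draws the cohort-level structure: news items (with shared durations and
#' word-onset annotations, as every subject hears the same stimuli), subject
#' labels with BDI-II scores, per-subject ratings, and the ground-truth
#' record of injected kernel parameters. EEG trials are *not* materialised
#' here (a study-size cohort would not fit in memory); use
#' [generate_subject_trials()] to synthesise one subject's trials
#' deterministically, or [write_cohort()] to stream everything to disk.
#'
#' @param config a [cohort_config()].
#' @param plan an [effect_plan()].
#' @return An object of class `cohort`: list with `config`, `plan`, `news`
#'   (news_id, condition, duration_s), `onsets` (news_id, onset_s, token),
#'   `subjects` (subject_id, group, bdi_score), `ratings` (long data frame),
#'   and `ground_truth` (see Details). `ground_truth$params` records, per
#'   subject x condition, the injected peak latencies and amplitudes of each
#'   component; `ground_truth$rating_means` the latent rating means.
#' @export
generate_cohort <- function(config = cohort_config(), plan = effect_plan()) {
  stopifnot(inherits(config, "cohort_config"), inherits(plan, "effect_plan"))
  set.seed(config$seed)
  conditions <- c("negative", "neutral", "positive")
  k <- config$n_trials_per_condition
  news <- data.frame(
    news_id = paste0(rep(substr(conditions, 1, 3), each = k), "_",
                     rep(seq_len(k), times = 3)),
    condition = rep(conditions, each = k),
    duration_s = round(runif(3 * k, config$trial_duration_s[1],
                             config$trial_duration_s[2]), 3),
    stringsAsFactors = FALSE)
  onsets <- do.call(rbind, lapply(seq_len(nrow(news)), function(i) {
    on <- generate_word_onsets(news$duration_s[i], config$word_rate_hz)
    if (!length(on)) return(NULL)
    data.frame(news_id = news$news_id[i], onset_s = round(on, 4),
               token = sprintf("w%03d", seq_along(on)),
               stringsAsFactors = FALSE)
  }))
  n_tot <- config$n_depressed + config$n_nondepressed
  subjects <- data.frame(
    subject_id = sprintf("sub_%03d", seq_len(n_tot)),
    group = rep(c("depressed", "non-depressed"),
                c(config$n_depressed, config$n_nondepressed)),
    stringsAsFactors = FALSE)
  bdi_dep <- pmin(pmax(round(rnorm(config$n_depressed, 21.1, 8.6)), 14), 63)
  bdi_non <- pmin(pmax(round(rnorm(config$n_nondepressed, 6.6, 3.3)), 0), 13)
  subjects$bdi_score <- c(bdi_dep, bdi_non)

  ratings <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
    df <- do.call(rbind, lapply(seq_len(nrow(news)), function(j) {
      r <- generate_ratings(subjects$group[i], news$condition[j], plan,
                            n = 1, effect_scale = config$effect_scale)
      cbind(data.frame(subject_id = subjects$subject_id[i],
                       news_id = news$news_id[j],
                       condition = news$condition[j],
                       stringsAsFactors = FALSE), r)
    }))
    df
  }))
  rownames(ratings) <- NULL

  params <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
    do.call(rbind, lapply(conditions, function(cond) {
      kp <- .kernel_params(subjects$group[i], cond, plan, config$effect_scale)
      data.frame(subject_id = subjects$subject_id[i],
                 group = subjects$group[i], condition = cond,
                 component = c("N1", "P2", "N400"),
                 latency_ms = c(kp$N1$peak_latency_ms, kp$P2$peak_latency_ms,
                                kp$N400$peak_latency_ms),
                 amplitude = c(kp$N1$amplitude, kp$P2$amplitude,
                               kp$N400$amplitude),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(params) <- NULL

  rating_means <- .rating_means()
  structure(list(config = config, plan = plan, news = news, onsets = onsets,
                 subjects = subjects, ratings = ratings,
                 ground_truth = list(params = params,
                                     rating_means = rating_means)),
            class = "cohort")
}

#' Materialise the EEG trials of one subject
#'
#' Deterministic given the cohort configuration: each subject has a private
#' RNG substream derived from the cohort seed, so the same subject always
#' yields byte-identical trials regardless of generation order.
#'
#' @param cohort a [generate_cohort()] result.
#' @param subject_id subject identifier.
#' @return Named list (by news_id) of `trial_recording` objects.
#' @export
generate_subject_trials <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "cohort"))
  i <- match(subject_id, cohort$subjects$subject_id)
  if (is.na(i)) stop("unknown subject_id: ", subject_id)
  group <- cohort$subjects$group[i]
  cfg <- cohort$config
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(.subject_seed(cfg$seed, i))
  out <- lapply(seq_len(nrow(cohort$news)), function(j) {
    news_id <- cohort$news$news_id[j]
    cond <- cohort$news$condition[j]
    kp <- .kernel_params(group, cond, cohort$plan, cfg$effect_scale)
    kernels <- lapply(kp, component_kernel, fs_hz = cfg$fs_hz)
    on <- cohort$onsets$onset_s[cohort$onsets$news_id == news_id]
    tr <- synthesize_trial(on, kernels, cfg$fs_hz, cohort$news$duration_s[j],
                           snr_db = cfg$snr_db)
    tr$news_id <- news_id
    tr$condition <- cond
    tr$subject_id <- subject_id
    tr
  })
  names(out) <- cohort$news$news_id
  out
}
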