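#' Preprocessing parameters
#'
#' Defaults follow the published chain: 1-50 Hz FIR band-pass of order 3300
#' at the native 500 Hz, resampling to 200 Hz, a 1-8 Hz FIR band-pass of
#' order 1320 (designed at 200 Hz, where it sits after resampling), and a
#' +-500 uV threshold-interpolation artifact cleaner standing in for
#' subspace/ICA artifact removal.
#'
#' @param bp1,bp2 length-2 passbands in Hz.
#' @param bp1_order,bp2_order FIR orders (even, so the band-pass has an odd,
#'   symmetric tap count).
#' @param resample_to target rate in Hz.
#' @param artifact_threshold_uv absolute amplitude threshold in uV.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(bp1 = c(1, 50), bp1_order = 3300,
                              resample_to = 200, bp2 = c(1, 8),
                              bp2_order = 1320,
                              artifact_threshold_uv = 500) {
  stopifnot(bp1_order %% 2 == 0, bp2_order %% 2 == 0,
            resample_to > 0, artifact_threshold_uv > 0)
  structure(list(bp1 = bp1, bp1_order = bp1_order,
                 resample_to = resample_to, bp2 = bp2,
                 bp2_order = bp2_order,
                 artifact_threshold_uv = artifact_threshold_uv),
            class = "preprocess_params")
}

# linear-phase FIR band-pass taps (Hamming window, via signal::fir1)
.fir_taps <- function(low_hz, high_hz, order, fs) {
  signal::fir1(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

# single-pass FIR convolution (FFT overlap) returning the same length as x
.fftfilt1 <- function(taps, x) {
  as.numeric(signal::fftfilt(taps, x))
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a linear-phase FIR band-pass forward and backward (filtfilt
#' style) so the net phase response is zero and component latencies are not
#' biased by group delay. The signal is reflection-padded by one filter
#' length at each end before filtering to suppress edge transients; output
#' length equals input length.
#'
#' @param x numeric signal (or channels x samples matrix).
#' @param low_hz,high_hz band edges, 0 < low < high < fs/2.
#' @param order FIR order (even); the signal must be longer than the filter.
#' @param fs sampling rate in Hz.
#' @return Filtered signal, same shape as `x`.
#' @export
fir_bandpass <- function(x, low_hz, high_hz, order, fs) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < fs / 2)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, fir_bandpass, low_hz = low_hz, high_hz = high_hz,
                   order = order, fs = fs))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  if (n <= order) {
    stop(sprintf("signal length (%d) must exceed the FIR order (%d)",
                 n, order))
  }
  taps <- .fir_taps(low_hz, high_hz, order, fs)
  pad <- min(order, n - 1L)
  xe <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- .fftfilt1(taps, xe)
  y <- rev(.fftfilt1(taps, rev(y)))
  y[(pad + 1):(pad + n)]
}

# rational approximation of a resampling ratio
.resample_ratio <- function(fs_from, fs_to) {
  p <- round(fs_to)
  q <- round(fs_from)
  if (abs(p - fs_to) > 1e-9 || abs(q - fs_from) > 1e-9) {
    stop("resampling requires (near-)integer sampling rates")
  }
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p = p / d, q = q / d)
}

#' Band-limited resampling
#'
#' Polyphase rational resampling: zero-stuff by p, apply a Kaiser-windowed
#' sinc low-pass at the tighter of the two Nyquist limits, and keep every
#' q-th sample, with exact compensation of the (integer) filter delay.
#' Content below the target Nyquist frequency is preserved.
#'
#' @param x numeric signal (or channels x samples matrix).
#' @param fs_from,fs_to source and target rates in Hz (`fs_from >= fs_to`).
#' @return Signal of length `round(n * fs_to / fs_from)`.
#' @export
resample_signal <- function(x, fs_from, fs_to) {
  if (fs_to <= 0) stop("fs_to must be > 0")
  stopifnot(fs_from >= fs_to)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, resample_signal, fs_from = fs_from, fs_to = fs_to))
    rownames(out) <- rownames(x)
    return(out)
  }
  n <- length(x)
  m <- round(n * fs_to / fs_from)
  if (fs_from == fs_to) return(x)
  r <- .resample_ratio(fs_from, fs_to)
  p <- r["p"]; q <- r["q"]
  # windowed-sinc low-pass in the upsampled domain
  half <- 10L * as.integer(max(p, q))
  cutoff <- 1 / max(p, q)            # fraction of upsampled Nyquist
  t <- (-half):half
  taps <- cutoff * .sinc(cutoff * t) * .kaiser_win(length(t), 8)
  taps <- taps * p / sum(taps)       # unity passband gain after zero-stuffing
  # odd-reflect the signal before zero-stuffing so edges stay clean
  padx <- min(as.integer(ceiling((half + q) / p)) + 1L, n - 1L)
  xe <- c(2 * x[1] - rev(x[2:(padx + 1)]), x,
          2 * x[n] - rev(x[(n - padx):(n - 1)]))
  up <- numeric(length(xe) * p)
  up[seq(1, by = p, length.out = length(xe))] <- xe
  y <- .fftfilt1(taps, up)
  # output sample k (0-based) sits at upsampled index padx*p + half + k*q
  pos <- padx * p + half + seq(0, by = q, length.out = m) + 1
  if (max(pos) > length(y)) y <- c(y, numeric(max(pos) - length(y)))
  y[pos]
}

# normalised sinc
.sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

.kaiser_win <- function(n, beta) {
  k <- 0:(n - 1)
  besselI(beta * sqrt(1 - (2 * k / (n - 1) - 1)^2), 0) / besselI(beta, 0)
}

#' Threshold-interpolation artifact rejection
#'
#' Samples whose absolute amplitude exceeds the threshold are located,
#' merged into contiguous windows and replaced by linear interpolation from
#' the neighbouring clean samples. A simple surrogate for subspace /
#' ICA-based transient-artifact removal: it targets the same
#' large-amplitude transients without modelling their sources.
#'
#' @param trial a `trial_recording` (or a numeric vector with `fs_hz`
#'   supplied).
#' @param threshold_uv absolute threshold (> 0), in the signal's units.
#' @param fs_hz sampling rate; taken from the trial when omitted.
#' @return The cleaned trial with attributes `rejection_mask` (data frame
#'   channel, start_s, end_s), `rejected_fraction` and `usable` (FALSE when
#'   more than half of any channel was rejected).
#' @export
reject_artifacts <- function(trial, threshold_uv, fs_hz = NULL) {
  stopifnot(threshold_uv > 0)
  if (inherits(trial, "trial_recording")) {
    sig <- trial$signal
    fs_hz <- trial$fs_hz
  } else {
    sig <- matrix(trial, nrow = 1, dimnames = list("x", NULL))
    if (is.null(fs_hz)) stop("fs_hz required for bare signals")
  }
  mask <- list()
  fracs <- numeric(nrow(sig))
  for (ch in seq_len(nrow(sig))) {
    x <- sig[ch, ]
    bad <- abs(x) > threshold_uv
    fracs[ch] <- mean(bad)
    if (any(bad)) {
      r <- rle(bad)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values)
      mask[[length(mask) + 1]] <- data.frame(
        channel = rownames(sig)[ch],
        start_s = (starts[runs] - 1) / fs_hz,
        end_s = ends[runs] / fs_hz, stringsAsFactors = FALSE)
      good <- which(!bad)
      if (length(good) >= 2) {
        sig[ch, bad] <- approx(good, x[good], xout = which(bad),
                               rule = 2)$y
      } else {
        sig[ch, bad] <- 0
      }
    }
  }
  mask <- if (length(mask)) do.call(rbind, mask) else
    data.frame(channel = character(0), start_s = numeric(0),
               end_s = numeric(0))
  if (inherits(trial, "trial_recording")) {
    trial$signal <- sig
    out <- trial
  } else {
    out <- sig[1, ]
  }
  attr(out, "rejection_mask") <- mask
  attr(out, "rejected_fraction") <- max(fracs)
  attr(out, "usable") <- max(fracs) <= 0.5
  if (max(fracs) > 0.5) {
    warning("more than 50% of samples exceeded the artifact threshold; ",
            "trial flagged unusable")
  }
  out
}

#' Full preprocessing chain for one trial
#'
#' Band-pass 1-50 Hz at the native rate, resample to 200 Hz, reject
#' large-amplitude artifacts, then band-pass 1-8 Hz.
#'
#' @param trial a `trial_recording`.
#' @param params a [preprocess_params()].
#' @return The preprocessed `trial_recording` at `params$resample_to` Hz,
#'   carrying the artifact attributes of [reject_artifacts()].
#' @export
preprocess_trial <- function(trial, params = preprocess_params()) {
  stopifnot(inherits(trial, "trial_recording"))
  fs0 <- trial$fs_hz
  sig <- fir_bandpass(trial$signal, params$bp1[1], params$bp1[2],
                      params$bp1_order, fs0)
  sig <- resample_signal(sig, fs0, params$resample_to)
  trial$signal <- sig
  trial$fs_hz <- params$resample_to
  trial <- reject_artifacts(trial, params$artifact_threshold_uv)
  atts <- attributes(trial)[c("rejection_mask", "rejected_fraction", "usable")]
  trial$signal <- fir_bandpass(trial$signal, params$bp2[1], params$bp2[2],
                               params$bp2_order, params$resample_to)
  for (a in names(atts)) attr(trial, a) <- atts[[a]]
  trial
}
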