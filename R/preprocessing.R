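#' Epoched EEG container
#'
#' Holds equal-length single-channel EEG trials together with the per-trial
#' noise variances and the normalised inverse-variance weights used by the
#' deconvolution: `b_n = (1 / sigma_n^2) / sum_m (1 / sigma_m^2)`, so noisier
#' trials contribute less to the averaged response.
#'
#' @param trials Numeric matrix, samples x trials (uV).
#' @param fs Sampling rate, Hz.
#' @param weights Optional explicit trial weights (normalised to sum to 1);
#'   by default the inverse-variance weights are computed from the trials.
#' @return An `epoched_eeg` object with fields `trials`, `fs`, `trial_len`,
#'   `sigma2`, `weights`, `n_trials`.
#' @export
epoched_eeg <- function(trials, fs, weights = NULL) {
  trials <- as.matrix(trials)
  check_finite(trials, "EEG trials")
  sigma2 <- unname(apply(trials, 2, var))
  if (any(sigma2 <= 0)) {
    abort(paste0("zero-variance trial(s): ",
                 paste(which(sigma2 <= 0), collapse = ", ")))
  }
  w <- if (is.null(weights)) {
    (1 / sigma2) / sum(1 / sigma2)
  } else {
    stopifnot(length(weights) == ncol(trials), all(weights > 0))
    weights / sum(weights)
  }
  structure(list(trials = trials, fs = fs,
                 trial_len = nrow(trials) / fs,
                 sigma2 = sigma2, weights = w,
                 n_trials = ncol(trials)),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat("<epoched_eeg> ", x$n_trials, " trials x ", format(x$trial_len),
      " s @ ", x$fs, " Hz; weight range [",
      format(min(x$weights), digits = 3), ", ",
      format(max(x$weights), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Filter raw EEG
#'
#' Offline preprocessing applied before epoching: a first-order high-pass at
#' 1 Hz removes slow drifts, then biquad notch filters (Q = 30) remove the
#' power line and its first three odd harmonics (60, 180, 300, 420 Hz by
#' default). Filters are causal by default, matching an acquisition-style
#' chain; set `zero_phase = TRUE` for forward-backward application.
#'
#' @param raw Numeric vector, raw EEG (uV).
#' @param fs Sampling rate, Hz; must be at least twice the highest notch.
#' @param hp_hz High-pass cutoff, Hz.
#' @param notch_hz Numeric vector of notch frequencies, Hz.
#' @param q Notch quality factor.
#' @param zero_phase Apply filters forward-backward instead of causally.
#' @return Filtered vector, same length as input.
#' @export
preprocess_eeg <- function(raw, fs, hp_hz = 1,
                           notch_hz = c(60, 180, 300, 420), q = 30,
                           zero_phase = FALSE) {
  check_finite(raw, "raw EEG")
  if (length(notch_hz) > 0 && fs < 2 * max(notch_hz)) {
    abort("fs must be at least twice the highest notch frequency")
  }
  hp <- signal::butter(1, hp_hz / (fs / 2), type = "high")
  apply_one <- function(b, a, x) {
    if (zero_phase) signal::filtfilt(signal::Arma(b = b, a = a), x)
    else as.numeric(signal::filter(b, a, x))
  }
  y <- apply_one(hp$b, hp$a, raw)
  for (f0 in notch_hz) {
    co <- notch_biquad(f0, fs, q)
    y <- apply_one(co$b, co$a, y)
  }
  y
}

#' Cut a recording into weighted trials
#'
#' Epochs a filtered recording at the given onsets and computes per-trial
#' sample variances and normalised inverse-variance weights. Overlapping
#' epochs are allowed.
#'
#' @param filtered Numeric vector (uV) after [preprocess_eeg()].
#' @param fs Sampling rate, Hz.
#' @param onsets Trial onset times, seconds.
#' @param trial_len Trial length, seconds; every `onset + trial_len` must fit
#'   inside the recording.
#' @return An [epoched_eeg].
#' @export
epoch_and_weight <- function(filtered, fs, onsets, trial_len) {
  ns <- round(trial_len * fs)
  starts <- round(onsets * fs) + 1L
  if (any(starts < 1) || any(starts + ns - 1L > length(filtered))) {
    abort("onsets + trial_len extend outside the recording")
  }
  trials <- vapply(starts, function(s) filtered[s:(s + ns - 1L)], numeric(ns))
  epoched_eeg(trials, fs)
}
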