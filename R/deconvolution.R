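#' Temporal response function container
#'
#' The deconvolved response (the speech-derived ABR): a waveform over lags,
#' in microvolts per regressor unit.
#'
#' @param lags Uniform lag grid, seconds, including 0.
#' @param weights Response amplitude per lag.
#' @param fs Sampling rate, Hz.
#' @param regressor_kind Which regressor produced it (free text).
#' @param n_trials Number of trials that entered the estimate.
#' @param meta Optional named list (subject, condition, ...).
#' @return An `abr_trf` object.
#' @export
abr_trf <- function(lags, weights, fs, regressor_kind = "", n_trials = NA_integer_,
                    meta = list()) {
  check_finite(weights, "TRF weights")
  if (!any(abs(lags) < 0.5 / fs)) abort("lag grid must include 0")
  structure(list(lags = lags, weights = weights, fs = fs,
                 regressor_kind = regressor_kind, n_trials = n_trials,
                 meta = meta),
            class = "abr_trf")
}

#' @export
print.abr_trf <- function(x, ...) {
  cat("<abr_trf", if (nzchar(x$regressor_kind)) paste0(" ", x$regressor_kind),
      "> lags [", format(min(x$lags)), ", ", format(max(x$lags)), "] s @ ",
      x$fs, " Hz", if (!is.na(x$n_trials)) paste0(", ", x$n_trials, " trials"),
      "\n", sep = "")
  invisible(x)
}

#' Weighted frequency-domain deconvolution
#'
#' Estimates the response (TRF) of the linear encoding model
#' `y = x (*) response + noise` across trials:
#' \deqn{response = F^{-1}\left\{ \frac{\sum_n b_n X_n^* Y_n}
#'   {\frac{1}{N}\sum_n X_n^* X_n + \epsilon} \right\}}
#' where `X_n`, `Y_n` are the FFTs of trial n's regressor and EEG, and `b_n`
#' the normalised inverse-variance trial weights carried by the
#' [epoched_eeg]. The FFT length equals the trial length, so the division is
#' circular; lags are unwrapped so negative lags read from the end of the
#' record, which is what makes pre-stimulus noise windows well defined.
#'
#' A small ridge `epsilon = eps_scale * mean(denominator)` guards against
#' spectral nulls of sparse regressors (pulse trains); set `eps_scale = 0`
#' for the bare estimator.
#'
#' @param regressor_trials A [regressor], or a list of them (one per trial).
#' @param eeg An [epoched_eeg] with matching rate and trial length.
#' @param lag_window Length-2 numeric, output lag range in seconds
#'   (default `c(-1, 1)`); must fit inside the trial.
#' @param eps_scale Relative ridge, default `1e-6`.
#' @return An [abr_trf].
#' @export
compute_trf <- function(regressor_trials, eeg, lag_window = c(-1, 1),
                        eps_scale = 1e-6) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  regs <- if (inherits(regressor_trials, "regressor")) {
    rep(list(regressor_trials), eeg$n_trials)
  } else regressor_trials
  if (length(regs) != eeg$n_trials) {
    abort("need one regressor per EEG trial (or a single shared regressor)")
  }
  n <- nrow(eeg$trials)
  for (i in seq_along(regs)) {
    r <- regs[[i]]
    if (!isTRUE(all.equal(r$fs, eeg$fs)) || length(r$samples) != n) {
      abort(paste0("regressor for trial ", i, " does not match the EEG grid"))
    }
    if (sum(r$samples^2) <= 1e-300) {
      abort(paste0("regressor for trial ", i, " has (near-)zero power"))
    }
  }
  fs <- eeg$fs
  num <- complex(n)
  den <- numeric(n)
  for (i in seq_along(regs)) {
    X <- fft(regs[[i]]$samples)
    Y <- fft(eeg$trials[, i])
    num <- num + eeg$weights[i] * Conj(X) * Y
    den <- den + Mod(X)^2
  }
  den <- den / eeg$n_trials
  eps <- eps_scale * mean(den)
  w <- Re(fft(num / (den + eps), inverse = TRUE)) / n

  n_neg <- round(-lag_window[1] * fs)
  n_pos <- round(lag_window[2] * fs)
  if (n_neg + n_pos + 1L > n) abort("lag_window longer than the trial")
  idx <- c(if (n_neg > 0) (n - n_neg + 1L):n, 1L:(n_pos + 1L))
  abr_trf(lags = seq(-n_neg, n_pos) / fs, weights = w[idx], fs = fs,
          regressor_kind = regs[[1]]$kind, n_trials = eeg$n_trials)
}

#' Average the responses to two stimulus polarities
#'
#' Sample-wise mean of the TRFs obtained from the positive and negative
#' stimulus polarities (HWR and ANM regressors), which cancels
#' polarity-following stimulus artifact while keeping the neural response.
#'
#' @param trf_pos,trf_neg [abr_trf] objects on identical lag grids.
#' @return An [abr_trf].
#' @export
average_polarities <- function(trf_pos, trf_neg) {
  stopifnot(inherits(trf_pos, "abr_trf"), inherits(trf_neg, "abr_trf"))
  if (length(trf_pos$lags) != length(trf_neg$lags) ||
      max(abs(trf_pos$lags - trf_neg$lags)) > 1e-12) {
    abort("lag grids differ")
  }
  kind <- sub("[+-]$", "", trf_pos$regressor_kind)
  abr_trf(trf_pos$lags, (trf_pos$weights + trf_neg$weights) / 2, trf_pos$fs,
          regressor_kind = kind,
          n_trials = trf_pos$n_trials, meta = trf_pos$meta)
}

#' Display high-pass filter for early ABR waves
#'
#' Zero-phase third-order Butterworth high-pass (default 150 Hz) applied to
#' the TRF waveform; removes the dominant low-frequency energy so waves I,
#' III and V become visible.
#'
#' @param trf An [abr_trf].
#' @param cutoff Cutoff, Hz; must be below Nyquist.
#' @param order Filter order.
#' @return A filtered [abr_trf].
#' @export
highpass_display <- function(trf, cutoff = 150, order = 3) {
  stopifnot(inherits(trf, "abr_trf"))
  if (cutoff >= trf$fs / 2) abort("cutoff must be below the Nyquist frequency")
  bt <- signal::butter(order, cutoff / (trf$fs / 2), type = "high")
  # forward-backward application with odd-reflection padding keeps edge
  # transients out of the displayed waveform
  x <- trf$weights
  n <- length(x)
  np <- min(n - 1, round(20 * trf$fs / cutoff))
  padded <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  fwd <- as.numeric(signal::filter(bt$b, bt$a, padded))
  bwd <- rev(as.numeric(signal::filter(bt$b, bt$a, rev(fwd))))
  w <- bwd[(np + 1):(np + n)]
  abr_trf(trf$lags, w, trf$fs, trf$regressor_kind, trf$n_trials, trf$meta)
}
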