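#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a TRF into a tibble
#'
#' @param x An [abr_trf].
#' @param ... Unused.
#' @return Tibble with columns `lag`, `amplitude`, `regressor`.
#' @export
tidy.abr_trf <- function(x, ...) {
  tibble::tibble(lag = x$lags, amplitude = x$weights,
                 regressor = x$regressor_kind)
}

#' @rdname tidy.abr_trf
#' @export
glance.abr_trf <- function(x, ...) {
  tibble::tibble(regressor = x$regressor_kind, fs = x$fs,
                 n_trials = x$n_trials, n_lags = length(x$lags),
                 lag_min = min(x$lags), lag_max = max(x$lags),
                 peak_lag = x$lags[which.max(abs(x$weights))],
                 peak_amplitude = x$weights[which.max(abs(x$weights))])
}

#' @export
tidy.snr_estimate <- function(x, ...) {
  tibble::tibble(snr_db = x$snr_db, defined = x$defined,
                 sigma_sn2 = x$sigma_sn2, sigma_n2 = x$sigma_n2)
}

#' @export
tidy.freq_snr <- function(x, ...) x$table

#' @export
tidy.coherence_result <- function(x, ...) {
  tibble::tibble(freq = x$freq, coherence = Mod(x$coherence),
                 phase = Arg(x$coherence),
                 noise_floor = x$noise_floor %||% NA_real_)
}

#' @export
glance.coherence_result <- function(x, ...) {
  tibble::tibble(n_bins = length(x$freq), bin_hz = x$freq[2] - x$freq[1],
                 n_slices = x$n_slices, slice_len = x$slice_len,
                 has_noise_floor = !is.null(x$noise_floor))
}

#' @export
tidy.epoched_eeg <- function(x, ...) {
  tibble::tibble(trial = seq_len(x$n_trials), sigma2 = x$sigma2,
                 weight = x$weights)
}

#' @export
tidy.abr_comparison <- function(x, ...) x$pairwise

#' @export
glance.abr_comparison <- function(x, ...) x$anova

#' @export
tidy.kernel_truth <- function(x, ...) {
  tibble::tibble(lag = x$lags, amplitude = x$amplitude)
}
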