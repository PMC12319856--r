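#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_hline
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a TRF waveform
#'
#' @param object An [abr_trf].
#' @param xlim Lag range to display, seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abr_trf <- function(object, xlim = c(-0.01, 0.03), ...) {
  d <- tidy(object)
  d <- d[d$lag >= xlim[1] & d$lag <= xlim[2], ]
  ggplot(d, aes(x = .data$lag * 1000, y = .data$amplitude)) +
    geom_line() +
    labs(x = "Lag (ms)", y = "Amplitude (µV / regressor unit)",
         title = paste("Derived response", object$regressor_kind)) +
    theme_minimal()
}

#' Plot per-frequency SNR (undefined bins break the line)
#'
#' @param object A `freq_snr` from [per_frequency_snr()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.freq_snr <- function(object, ...) {
  ggplot(object$table, aes(x = .data$freq, y = .data$snr_db)) +
    geom_line(na.rm = FALSE) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "Frequency (Hz)", y = "SNR (dB)") +
    theme_minimal()
}

#' Plot coherence magnitude with its noise floor
#'
#' @param object A `coherence_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherence_result <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$freq, y = .data$coherence)) +
    geom_line() +
    labs(x = "Frequency (Hz)", y = "|Coherence|") +
    theme_minimal()
  if (!is.null(object$noise_floor)) {
    p <- p + geom_line(aes(y = .data$noise_floor), linetype = "dashed")
  }
  p
}

#' Plot a time-to-criterion curve
#'
#' @param object A `ttc_curve` from [time_to_criterion()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ttc_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$duration_min, y = .data$proportion)) +
    geom_step() +
    labs(x = "Recording duration (min)",
         y = "Cumulative proportion of subjects at criterion") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
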