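#' Regressor container
#'
#' A deconvolution input: a stimulus feature sampled on the EEG time base.
#'
#' @param samples Numeric vector of feature samples.
#' @param fs Sampling rate, Hz (the EEG rate, 10 kHz by convention).
#' @param kind One of `"HWR+"`, `"HWR-"`, `"GP"`, `"ANM+"`, `"ANM-"`.
#' @param units Free-text units (dimensionless pressure, impulses, spikes/s).
#' @return A `regressor` object.
#' @export
regressor <- function(samples, fs, kind, units = "") {
  check_finite(samples, "regressor samples")
  kind <- match.arg(kind, c("HWR+", "HWR-", "GP", "ANM+", "ANM-"))
  # every regressor kind is nonnegative by construction
  if (any(samples < 0)) abort("regressor samples must be nonnegative")
  structure(list(samples = samples, fs = fs, kind = kind, units = units),
            class = "regressor")
}

#' @export
print.regressor <- function(x, ...) {
  cat("<regressor ", x$kind, "> ", length(x$samples), " samples @ ",
      x$fs, " Hz", if (nzchar(x$units)) paste0(" [", x$units, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Half-wave rectified stimulus regressors
#'
#' Rectifies the stimulus waveform (positive part for HWR+, inverted-negative
#' part for HWR-) and resamples each to the EEG rate with a zero-phase
#' Fourier-domain anti-aliased resampler, so no group delay is introduced
#' into the response latencies. Tiny negative ripples from the band-limited
#' resampling of a rectified signal are clamped to zero.
#'
#' @param audio Numeric stimulus waveform.
#' @param fs_audio Audio sampling rate, Hz.
#' @param fs_out Output (EEG) rate, Hz.
#' @return A list with elements `pos` and `neg`, both [regressor] objects.
#' @export
hwr_regressor <- function(audio, fs_audio, fs_out = 10000) {
  check_finite(audio, "audio")
  if (length(audio) == 0 || all(audio == 0)) abort("audio is silent or empty")
  half <- function(x) pmax(resample_fft(x, fs_audio, fs_out), 0)
  list(pos = regressor(half(pmax(audio, 0)), fs_out, "HWR+", "pressure (a.u.)"),
       neg = regressor(half(pmax(-audio, 0)), fs_out, "HWR-", "pressure (a.u.)"))
}

#' Glottal pulse train regressor
#'
#' Unit impulses at the glottal pulse times, rounded to the nearest sample
#' (ties to even); pulses that round to the same sample accumulate.
#'
#' @param pulse_times Sorted pulse times, seconds, within `[0, duration)`.
#' @param duration Trial duration, seconds.
#' @param fs Output rate, Hz.
#' @return A [regressor] of kind `"GP"`.
#' @export
gp_regressor <- function(pulse_times, duration, fs = 10000) {
  if (is.unsorted(pulse_times)) abort("pulse_times must be sorted")
  bad <- pulse_times < 0 | pulse_times >= duration
  if (any(bad)) {
    abort(paste0("pulse time(s) outside [0, duration): ",
                 paste(format(pulse_times[bad]), collapse = ", ")))
  }
  n <- round(duration * fs)
  idx <- round(pulse_times * fs) + 1L
  idx[idx > n] <- n
  samples <- numeric(n)
  if (length(idx) > 0) {
    tab <- tabulate(idx, nbins = n)
    samples <- as.numeric(tab)
  }
  regressor(samples, fs, "GP", "impulses")
}

#' Periphery model configuration
#'
#' Characteristic-frequency grid and level settings for the auditory-nerve
#' regressor. Defaults follow standard practice: 125 Hz to 16 kHz at 1/6
#' octave spacing (43 CFs), high-spontaneous-rate fibers, stimulus presented
#' at 65 dB SPL (reference 20 uPa, RMS over the full stimulus).
#'
#' @param cf_lo,cf_hi CF range, Hz (`cf_lo < cf_hi`).
#' @param cf_spacing Spacing in octaves, > 0.
#' @param fiber_type Only `"HSR"` is modelled.
#' @param level_db_spl Presentation level, dB SPL.
#' @param backend `"bundled_simple"` for the built-in periphery,
#'   `"external_adapter"` to require a user-registered backend, or directly a
#'   function `(audio_pa, fs, cfs) -> rate matrix` (samples x CFs, spikes/s).
#' @return A `periphery_config` object.
#' @export
periphery_config <- function(cf_lo = 125, cf_hi = 16000, cf_spacing = 1 / 6,
                             fiber_type = "HSR", level_db_spl = 65,
                             backend = "bundled_simple") {
  stopifnot(cf_lo > 0, cf_lo <= cf_hi, cf_spacing > 0)
  fiber_type <- match.arg(fiber_type, "HSR")
  structure(list(cf_lo = cf_lo, cf_hi = cf_hi, cf_spacing = cf_spacing,
                 fiber_type = fiber_type, level_db_spl = level_db_spl,
                 backend = backend),
            class = "periphery_config")
}

#' Characteristic-frequency grid
#'
#' Geometric grid from `cf_lo` to `cf_hi` at `2^cf_spacing` ratio; the upper
#' edge is included when it falls on the grid (the defaults give 43 CFs over
#' 7 octaves).
#'
#' @param config A [periphery_config].
#' @return Numeric vector of CFs in Hz.
#' @export
cf_grid <- function(config = periphery_config()) {
  n_oct <- log2(config$cf_hi / config$cf_lo)
  k <- floor(n_oct / config$cf_spacing + 1e-9)
  config$cf_lo * 2^(config$cf_spacing * (0:k))
}

#' Auditory-nerve-model regressor
#'
#' Passes the stimulus through a simplified auditory periphery and returns
#' the instantaneous firing rate summed across characteristic frequencies of
#' high-spontaneous-rate fibers, resampled to the EEG rate. The stimulus is
#' sign-flipped for the negative polarity, upsampled to the model rate
#' (100 kHz), scaled to a pascal pressure waveform at the configured dB SPL,
#' and processed per CF by the bundled periphery (gammatone filterbank,
#' inner-hair-cell rectification and 3 kHz low-pass, three-store
#' transmitter-depletion adaptation); see [anm_lite()]. The spontaneous-rate
#' baseline is retained by default.
#'
#' @param audio Stimulus waveform (any units; level is set by `config`).
#' @param fs_audio Audio sampling rate, Hz.
#' @param config A [periphery_config].
#' @param polarity `"+"` or `"-"`.
#' @param fs_out Output (EEG) rate, Hz.
#' @param fs_model Periphery model rate, Hz.
#' @param subtract_spont Subtract the resting rate before output (off by
#'   default: the summed firing rate itself is the regressor).
#' @return A [regressor] of kind `"ANM+"` or `"ANM-"` in spikes/s.
#' @export
anm_regressor <- function(audio, fs_audio, config = periphery_config(),
                          polarity = c("+", "-"), fs_out = 10000,
                          fs_model = 1e5, subtract_spont = FALSE) {
  polarity <- match.arg(polarity)
  check_finite(audio, "audio")
  if (length(audio) == 0) abort("audio is empty")
  x <- if (polarity == "-") -audio else audio
  x <- resample_fft(x, fs_audio, fs_model)
  # scale to pascals at the requested sound pressure level (ref 20 uPa RMS)
  r <- rms(x)
  if (r > 0) x <- x / r * 20e-6 * 10^(config$level_db_spl / 20)
  cfs <- cf_grid(config)

  backend <- config$backend
  rate_sum <- if (is.function(backend)) {
    rowSums(backend(x, fs_model, cfs))
  } else if (identical(backend, "bundled_simple")) {
    summed <- numeric(length(x))
    for (cf in cfs) summed <- summed + anm_lite(x, fs_model, cf)
    summed
  } else if (identical(backend, "external_adapter")) {
    abort(paste0("no external periphery adapter registered; pass a function ",
                 "as `backend` or use backend = \"bundled_simple\""))
  } else {
    abort(paste0("unknown periphery backend: ", backend))
  }
  if (subtract_spont) rate_sum <- rate_sum - sum(anm_lite_spont_rate(cfs))
  y <- pmax(resample_fft(rate_sum, fs_model, fs_out), 0)
  regressor(y, fs_out, paste0("ANM", polarity), "spikes/s")
}
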