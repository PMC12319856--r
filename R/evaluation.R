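#' Broadband response SNR
#'
#' Signal-plus-noise variance is the sample variance of the TRF over the
#' signal window (0-15 ms by default, where the ABR lives); noise variance is
#' the mean variance over every full non-overlapping 15-ms segment of the
#' pre-stimulus baseline (-1000 to -500 ms, i.e. 33 segments). Then
#' `SNR = 10 log10((sigma_SN^2 - sigma_N^2) / sigma_N^2)` in dB. When the
#' signal-window variance does not exceed the baseline the log argument is
#' negative and the SNR is undefined: `snr_db` is `NA` and `defined` is
#' `FALSE` — no error is raised, and the marker must be propagated by
#' downstream summaries.
#'
#' @param trf An [abr_trf] whose lag range covers both windows.
#' @param signal_window,noise_window Length-2 numerics, seconds.
#' @param seg_len Baseline segment length, seconds (equals the signal window
#'   length by construction).
#' @return An `snr_estimate` object: fields `snr_db`, `defined`, `sigma_sn2`,
#'   `sigma_n2`, `signal_window`, `noise_window`.
#' @export
broadband_snr <- function(trf, signal_window = c(0, 0.015),
                          noise_window = c(-1, -0.5), seg_len = 0.015) {
  stopifnot(inherits(trf, "abr_trf"))
  lo <- min(trf$lags); hi <- max(trf$lags)
  if (signal_window[1] < lo - 1e-9 || signal_window[2] > hi + 1e-9 ||
      noise_window[1] < lo - 1e-9 || noise_window[2] > hi + 1e-9) {
    abort("signal/noise windows fall outside the TRF lag range")
  }
  sig <- trf_segment(trf, signal_window[1], signal_window[2])
  s2_sn <- var(sig)
  segs <- baseline_segments(trf, noise_window, seg_len)
  s2_n <- mean(vapply(segs, var, numeric(1)))
  ratio <- (s2_sn - s2_n) / s2_n
  structure(list(snr_db = if (ratio > 0) 10 * log10(ratio) else NA_real_,
                 defined = ratio > 0,
                 sigma_sn2 = s2_sn, sigma_n2 = s2_n,
                 signal_window = signal_window, noise_window = noise_window),
            class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  cat("<snr_estimate> ",
      if (x$defined) paste0(format(x$snr_db, digits = 4), " dB")
      else "undefined (signal variance below baseline)", "\n", sep = "")
  invisible(x)
}

# half-open [from, to) segment of the TRF waveform
trf_segment <- function(trf, from, to) {
  idx <- trf$lags >= from - 1e-12 & trf$lags < to - 1e-12
  trf$weights[idx]
}

baseline_segments <- function(trf, noise_window, seg_len) {
  n_seg <- floor((noise_window[2] - noise_window[1]) / seg_len + 1e-9)
  lapply(seq_len(n_seg) - 1, function(k) {
    trf_segment(trf, noise_window[1] + k * seg_len,
                noise_window[1] + (k + 1) * seg_len)
  })
}

#' Per-frequency response SNR
#'
#' Same construction as [broadband_snr()] but per frequency bin: single-taper
#' (first Slepian, 67 Hz full bandwidth) power spectral densities of the
#' 15-ms signal segment and of each baseline segment (averaged), then
#' `SNR(f) = 10 log10((P_SN(f) - P_N(f)) / P_N(f))`. Bins where the baseline
#' power exceeds the signal power are undefined and reported as `NA` (the
#' broken-line bins when plotted), never dropped.
#'
#' @inheritParams broadband_snr
#' @param bandwidth_hz Full spectral bandwidth of the taper, Hz.
#' @return A `freq_snr` object wrapping a tibble with columns `freq`,
#'   `p_signal`, `p_noise`, `snr_db`.
#' @export
per_frequency_snr <- function(trf, signal_window = c(0, 0.015),
                              noise_window = c(-1, -0.5), seg_len = 0.015,
                              bandwidth_hz = 67) {
  stopifnot(inherits(trf, "abr_trf"))
  sig <- trf_segment(trf, signal_window[1], signal_window[2])
  segs <- baseline_segments(trf, noise_window, seg_len)
  ps <- taper_psd(sig, trf$fs, bandwidth_hz)
  pn_mat <- vapply(segs, function(s) taper_psd(s, trf$fs, bandwidth_hz)$psd,
                   numeric(length(ps$psd)))
  pn <- rowMeans(pn_mat)
  ratio <- (ps$psd - pn) / pn
  snr_db <- rep(NA_real_, length(ratio))
  snr_db[ratio > 0] <- 10 * log10(ratio[ratio > 0])
  tbl <- tibble::tibble(freq = ps$freq, p_signal = ps$psd, p_noise = pn,
                        snr_db = snr_db)
  structure(list(table = tbl, bandwidth_hz = bandwidth_hz), class = "freq_snr")
}

#' @export
print.freq_snr <- function(x, ...) {
  cat("<freq_snr> ", nrow(x$table), " bins, ",
      sum(!is.na(x$table$snr_db)), " defined\n", sep = "")
  print(x$table, n = 5)
  invisible(x)
}

#' Broadband SNR as a function of recording duration
#'
#' Recomputes the TRF on nested prefixes of the trial sequence (the first
#' k trials approximate the first `duration` minutes of recording) and
#' returns the broadband SNR at each duration. Feeds [time_to_criterion()].
#'
#' @param regressor_trials As in [compute_trf()].
#' @param eeg An [epoched_eeg].
#' @param durations_min Recording durations to evaluate, minutes (each is
#'   rounded up to a whole number of trials).
#' @param ... Passed to [compute_trf()] and [broadband_snr()] via names
#'   `lag_window`, `signal_window`, `noise_window`.
#' @return Tibble with columns `duration_min`, `n_trials`, `snr_db`.
#' @export
snr_by_duration <- function(regressor_trials, eeg, durations_min, ...) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  regs <- if (inherits(regressor_trials, "regressor")) {
    rep(list(regressor_trials), eeg$n_trials)
  } else regressor_trials
  rows <- purrr::map(sort(durations_min), function(d) {
    k <- min(eeg$n_trials, max(1L, ceiling(d * 60 / eeg$trial_len)))
    sub <- epoched_eeg(eeg$trials[, seq_len(k), drop = FALSE], eeg$fs)
    trf <- compute_trf(regs[seq_len(k)], sub, ...)
    s <- broadband_snr(trf)
    tibble::tibble(duration_min = d, n_trials = k, snr_db = s$snr_db)
  })
  dplyr::bind_rows(rows)
}

#' Cumulative time-to-criterion curve
#'
#' For each recording duration, the proportion of subjects whose response
#' reached the SNR criterion at that duration or any shorter one, so the
#' curve is non-decreasing by construction. Undefined SNRs count as not
#' having reached criterion.
#'
#' @param snr_table Tibble with columns `subject`, `duration_min`, `snr_db`
#'   (e.g. [snr_by_duration()] rows bound across subjects). Every subject
#'   must be evaluated on the same duration grid.
#' @param criterion_db SNR criterion, dB.
#' @return A tibble (class `ttc_curve`) with columns `duration_min`,
#'   `proportion`.
#' @export
time_to_criterion <- function(snr_table, criterion_db = 0) {
  needed <- c("subject", "duration_min", "snr_db")
  if (!all(needed %in% names(snr_table))) {
    abort("snr_table needs columns subject, duration_min, snr_db")
  }
  grids <- snr_table |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(g = paste(sort(unique(.data$duration_min)), collapse = ","))
  if (dplyr::n_distinct(grids$g) != 1) {
    abort("subjects were evaluated on different (non-nested) duration grids")
  }
  out <- snr_table |>
    dplyr::mutate(hit = !is.na(.data$snr_db) & .data$snr_db >= criterion_db) |>
    dplyr::arrange(.data$subject, .data$duration_min) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(achieved = cumsum(.data$hit) > 0) |>
    dplyr::group_by(.data$duration_min) |>
    dplyr::summarise(proportion = mean(.data$achieved))
  class(out) <- c("ttc_curve", class(out))
  out
}

#' Predict EEG from a TRF kernel
#'
#' Restricts the TRF to a kernel window (zero outside; `[0, 15]` ms for the
#' subcortical kernel, `[0, 200]` ms for the full kernel), then linearly
#' convolves it with each trial's regressor, truncated to the trial length.
#'
#' @param trf An [abr_trf].
#' @param regressor_trials A [regressor] or list of them.
#' @param kernel_window Length-2 numeric, seconds, inside the TRF lag range.
#' @return Numeric matrix, samples x trials, of predicted EEG.
#' @export
predict_eeg <- function(trf, regressor_trials, kernel_window = c(0, 0.015)) {
  stopifnot(inherits(trf, "abr_trf"))
  if (kernel_window[1] < min(trf$lags) - 1e-9 ||
      kernel_window[2] > max(trf$lags) + 1e-9) {
    abort("kernel_window falls outside the TRF lag range")
  }
  regs <- if (inherits(regressor_trials, "regressor")) list(regressor_trials)
          else regressor_trials
  keep <- trf$lags >= kernel_window[1] - 1e-12 &
    trf$lags <= kernel_window[2] + 1e-12
  k <- trf$weights[keep]
  offset <- round(trf$lags[keep][1] * trf$fs)
  pred <- vapply(regs, function(r) {
    n <- length(r$samples)
    cv <- convolve_fft(r$samples, k)
    idx <- seq_len(n) - offset
    out <- numeric(n)
    ok <- idx >= 1 & idx <= length(cv)
    out[ok] <- cv[idx[ok]]
    out
  }, numeric(length(regs[[1]]$samples)))
  pred
}

#' Prediction accuracy (Pearson correlation)
#'
#' Pearson r between predicted and recorded EEG, computed per trial and
#' averaged (unweighted) across trials. Optionally both signals are first
#' high-pass filtered at 40 Hz (first-order Butterworth, causal) to
#' de-emphasise slow cortical activity.
#'
#' @param predicted,real Numeric matrices, samples x trials, equal sizes.
#' @param fs Sampling rate, Hz (needed when `highpass_40hz = TRUE`).
#' @param highpass_40hz Apply the 40 Hz high-pass before correlating.
#' @return Mean Pearson r (length-1 numeric) with per-trial values in
#'   attribute `"per_trial"`.
#' @export
prediction_accuracy <- function(predicted, real, fs = NULL,
                                highpass_40hz = FALSE) {
  predicted <- as.matrix(predicted); real <- as.matrix(real)
  if (!all(dim(predicted) == dim(real))) abort("signals differ in size")
  if (highpass_40hz) {
    if (is.null(fs)) abort("fs is required for the 40 Hz high-pass")
    hp <- signal::butter(1, 40 / (fs / 2), type = "high")
    predicted <- apply(predicted, 2, function(x)
      as.numeric(signal::filter(hp$b, hp$a, x)))
    real <- apply(real, 2, function(x)
      as.numeric(signal::filter(hp$b, hp$a, x)))
  }
  rs <- vapply(seq_len(ncol(real)), function(j) {
    if (sd(predicted[, j]) == 0 || sd(real[, j]) == 0) {
      abort(paste0("zero-variance input in trial ", j))
    }
    cor(predicted[, j], real[, j])
  }, numeric(1))
  structure(mean(rs), per_trial = rs)
}

#' Spectral coherence between predicted and recorded EEG
#'
#' Both signals are cut into non-overlapping slices (0.2 s by default, giving
#' 5 Hz bins), pooled across trials, and the complex coherence per bin is
#' `C(f) = E[X*(f) Y(f)] / sqrt(E[|X(f)|^2] E[|Y(f)|^2])` with the
#' expectation over slices; |C| <= 1 by Cauchy-Schwarz. The DC bin is kept.
#'
#' @param predicted,real Numeric matrices, samples x trials.
#' @param fs Sampling rate, Hz.
#' @param slice_len Slice length, seconds; must fit inside a trial.
#' @return A `coherence_result`: fields `freq` (Hz), `coherence` (complex),
#'   `n_slices`, `slice_len`, `noise_floor` (NULL until attached).
#' @export
spectral_coherence <- function(predicted, real, fs, slice_len = 0.2) {
  predicted <- as.matrix(predicted); real <- as.matrix(real)
  if (!all(dim(predicted) == dim(real))) abort("signals differ in size")
  ns <- round(slice_len * fs)
  if (ns > nrow(real)) abort("slice_len longer than a trial")
  sl <- pooled_slices(predicted, ns)
  rl <- pooled_slices(real, ns)
  nf <- ns %/% 2 + 1L
  sxy <- complex(nf); sxx <- numeric(nf); syy <- numeric(nf)
  for (i in seq_along(sl)) {
    X <- fft(sl[[i]])[seq_len(nf)]
    Y <- fft(rl[[i]])[seq_len(nf)]
    sxy <- sxy + Conj(X) * Y
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
  }
  coh <- sxy / sqrt(sxx * syy)
  coh[sxx == 0 | syy == 0] <- NA_complex_
  structure(list(freq = (seq_len(nf) - 1) * fs / ns, coherence = coh,
                 n_slices = length(sl), slice_len = slice_len,
                 noise_floor = NULL),
            class = "coherence_result")
}

pooled_slices <- function(mat, ns) {
  k <- nrow(mat) %/% ns
  out <- vector("list", k * ncol(mat))
  m <- 0L
  for (j in seq_len(ncol(mat))) {
    for (i in seq_len(k)) {
      m <- m + 1L
      out[[m]] <- mat[((i - 1L) * ns + 1L):(i * ns), j]
    }
  }
  out
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("<coherence_result> ", length(x$freq), " bins (",
      format(x$freq[2] - x$freq[1]), " Hz spacing), ", x$n_slices,
      " slices", if (!is.null(x$noise_floor)) ", noise floor attached",
      "\n", sep = "")
  invisible(x)
}

#' Shuffled-pairing coherence noise floor
#'
#' Re-pairs predicted and recorded trials at random so no trial keeps its own
#' partner, computes the coherence of each mismatched pairing, and returns
#' the per-bin median magnitude across shuffles: the chance level of the
#' coherence estimate.
#'
#' @inheritParams spectral_coherence
#' @param n_shuffles Number of mismatched pairings.
#' @param seed Integer seed.
#' @return The `coherence_result` for the matched pairing with its
#'   `noise_floor` field set (per-bin median magnitude).
#' @export
coherence_noise_floor <- function(predicted, real, fs, slice_len = 0.2,
                                  n_shuffles = 20, seed = 1) {
  predicted <- as.matrix(predicted); real <- as.matrix(real)
  n_tr <- ncol(real)
  if (n_tr < 2) abort("need at least two trials to mismatch pairings")
  set.seed(seed)
  floor_mat <- matrix(NA_real_, round(slice_len * fs) %/% 2 + 1L, n_shuffles)
  for (s in seq_len(n_shuffles)) {
    repeat {
      p <- sample(n_tr)
      if (!any(p == seq_len(n_tr))) break
    }
    ch <- spectral_coherence(predicted, real[, p, drop = FALSE], fs, slice_len)
    floor_mat[, s] <- Mod(ch$coherence)
  }
  res <- spectral_coherence(predicted, real, fs, slice_len)
  res$noise_floor <- apply(floor_mat, 1, median)
  res
}

#' Mean coherence magnitude per frequency band
#'
#' Averages |C(f)| over the bins whose centre lies inside each closed band.
#' Defaults are the bands where the auditory-nerve regressor shows an
#' advantage: 0-20, 40-60 and 80-120 Hz; an alternative wider partition
#' (0-25, 25-85, 85-135 Hz) can be passed instead.
#'
#' @param coherence A `coherence_result`.
#' @param bands List of length-2 numerics, Hz, each within Nyquist.
#' @return Tibble with columns `band_lo`, `band_hi`, `n_bins`,
#'   `mean_coherence`.
#' @export
band_means <- function(coherence,
                       bands = list(c(0, 20), c(40, 60), c(80, 120))) {
  stopifnot(inherits(coherence, "coherence_result"))
  rows <- purrr::map(bands, function(b) {
    idx <- coherence$freq >= b[1] - 1e-9 & coherence$freq <= b[2] + 1e-9
    if (!any(idx)) abort(paste0("band [", b[1], ", ", b[2], "] Hz contains no bins"))
    tibble::tibble(band_lo = b[1], band_hi = b[2], n_bins = sum(idx),
                   mean_coherence = mean(Mod(coherence$coherence[idx])))
  })
  dplyr::bind_rows(rows)
}

#' Welch power spectral density of a regressor
#'
#' Hann-windowed Welch estimate (1-s segments, 50% overlap by default) of the
#' regressor waveform; useful for seeing how each regressor's spectrum shapes
#' the deconvolved response.
#'
#' @param reg A [regressor].
#' @param seg_len_s Segment length, seconds.
#' @param overlap Fractional overlap.
#' @return Tibble with columns `freq`, `psd`, `n_segments`.
#' @export
regressor_psd <- function(reg, seg_len_s = 1, overlap = 0.5) {
  stopifnot(inherits(reg, "regressor"))
  welch_psd(reg$samples, reg$fs, seg_len_s, overlap)
}
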