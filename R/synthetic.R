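#' Default ABR wave components
#'
#' Canonical components of a speech-evoked ABR kernel: waves I, III and V at
#' ABR-like latencies plus a slow cortical deflection. Latencies for waves I
#' and V follow the morphology typically reported for speech-derived ABRs
#' (wave I near 3.2 ms, wave V near 7.2 ms); wave III is placed between them.
#' Amplitudes are in microvolts per regressor unit, widths are Gaussian
#' standard deviations in seconds.
#'
#' @return A tibble with columns `label`, `latency`, `amplitude`, `width`.
#' @export
abr_wave_components <- function() {
  tibble::tibble(
    label    = c("I", "III", "V", "cortical"),
    latency  = c(0.0032, 0.0052, 0.0072, 0.100),
    amplitude = c(0.15, 0.20, 0.35, 0.80),
    width    = c(0.00025, 0.00025, 0.0005, 0.020)
  )
}

#' Construct a ground-truth ABR kernel
#'
#' Builds a known impulse response as a sum of Gaussian bumps, one per wave
#' component, on a uniform lag grid at the EEG sampling rate. The kernel is
#' the quantity deconvolution should recover, so keeping it parametric and
#' exact makes recovery tests sharp.
#'
#' @param wave_components Tibble/data frame with columns `label`, `latency`
#'   (s), `amplitude` (uV per regressor unit) and `width` (s, Gaussian sd).
#'   Defaults to [abr_wave_components()]. May have zero rows (zero kernel).
#' @param lag_range Length-2 numeric, kernel support in seconds. Must cover
#'   every component latency.
#' @param fs Sampling rate in Hz.
#' @param seed Stored for provenance; the construction is deterministic.
#' @return A `kernel_truth` object with fields `lags`, `amplitude`, `fs`,
#'   `wave_components`, `seed`.
#' @export
make_kernel <- function(wave_components = abr_wave_components(),
                        lag_range = c(0, 0.25), fs = 10000, seed = NULL) {
  stopifnot(fs > 0, length(lag_range) == 2, lag_range[1] < lag_range[2])
  wc <- tibble::as_tibble(wave_components)
  if (nrow(wc) > 0) {
    bad <- wc$latency < lag_range[1] | wc$latency > lag_range[2]
    if (any(bad)) {
      abort(paste0("wave component(s) outside lag_range: ",
                   paste(wc$label[bad], collapse = ", ")))
    }
  }
  lags <- seq(round(lag_range[1] * fs), round(lag_range[2] * fs)) / fs
  amp <- numeric(length(lags))
  for (i in seq_len(nrow(wc))) {
    amp <- amp + wc$amplitude[i] * exp(-(lags - wc$latency[i])^2 / (2 * wc$width[i]^2))
  }
  structure(list(lags = lags, amplitude = amp, fs = fs,
                 wave_components = wc, seed = seed),
            class = "kernel_truth")
}

#' @export
print.kernel_truth <- function(x, ...) {
  cat("<kernel_truth> ", length(x$lags), " lags [",
      format(min(x$lags)), ", ", format(max(x$lags)), "] s @ ", x$fs, " Hz, ",
      nrow(x$wave_components), " components\n", sep = "")
  invisible(x)
}

#' Generate a pulse-excited pseudo-speech stimulus
#'
#' Emulates the statistical structure of voiced speech that the regressors
#' consume: a band-limited glottal-pulse train with jittered fundamental
#' frequency inside voiced spans, shaped by a slow random amplitude envelope,
#' plus low-level noise (-20 dB relative to voiced RMS) in unvoiced spans.
#' No attempt is made at intelligibility.
#'
#' @param duration Seconds, > 0.
#' @param f0_mean,f0_sd Mean and jitter (Hz) of the fundamental frequency.
#' @param voiced_fraction Fraction of the duration that is voiced, in (0, 1].
#' @param fs_audio Audio sampling rate (Hz); must exceed `4 * f0_mean`.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A `pseudo_speech` object with fields `audio`, `fs`, `pulse_times`,
#'   `voiced_mask`, `f0_track`, `seed`.
#' @export
make_pseudo_speech <- function(duration, f0_mean = 110, f0_sd = 10,
                               voiced_fraction = 0.6, fs_audio = 44100,
                               seed = 1) {
  stopifnot(duration > 0, f0_mean > 0, f0_sd >= 0,
            voiced_fraction > 0, voiced_fraction <= 1)
  if (fs_audio < 4 * f0_mean) {
    abort("fs_audio must be at least 4 * f0_mean (excitation would be undersampled)")
  }
  set.seed(seed)
  n <- round(duration * fs_audio)

  # Alternating voiced/unvoiced spans with exponential lengths whose means
  # are chosen so the expected voiced fraction matches the request.
  mean_voiced <- 0.35
  mean_unvoiced <- mean_voiced * (1 - voiced_fraction) / voiced_fraction
  voiced_mask <- logical(n)
  t0 <- 0
  voiced_now <- TRUE
  spans <- list()
  while (t0 < duration) {
    len <- if (voiced_fraction == 1) {
      duration
    } else if (voiced_now) rexp(1, 1 / mean_voiced) else rexp(1, 1 / mean_unvoiced)
    t1 <- min(t0 + len, duration)
    if (voiced_now) spans[[length(spans) + 1L]] <- c(t0, t1)
    i0 <- floor(t0 * fs_audio) + 1L
    i1 <- min(n, ceiling(t1 * fs_audio))
    if (i1 >= i0) voiced_mask[i0:i1] <- voiced_now
    t0 <- t1
    voiced_now <- !voiced_now
  }

  # Pulse times: march through each voiced span at intervals 1/f0 with
  # Gaussian jitter on f0.
  pulse_times <- numeric(0)
  pulse_f0 <- numeric(0)
  for (sp in spans) {
    end <- min(sp[2], duration)
    if (f0_sd == 0) {
      # exact arithmetic grid: no floating-point accumulation drift
      k <- 0:floor((end - sp[1]) * f0_mean)
      t <- sp[1] + k / f0_mean
      t <- t[t < end]
      pulse_times <- c(pulse_times, t)
      pulse_f0 <- c(pulse_f0, rep(f0_mean, length(t)))
    } else {
      t <- sp[1]
      while (t < end) {
        f0 <- max(f0_mean + rnorm(1, 0, f0_sd), f0_mean / 4)
        pulse_times <- c(pulse_times, t)
        pulse_f0 <- c(pulse_f0, f0)
        t <- t + 1 / f0
      }
    }
  }

  # Band-limited excitation: impulses smoothed by a Hann-windowed sinc.
  exc <- numeric(n)
  idx <- pmin(n, round(pulse_times * fs_audio) + 1L)
  for (i in seq_along(idx)) exc[idx[i]] <- exc[idx[i]] + 1
  fc <- min(8000, 0.45 * fs_audio)
  half <- 64L
  tt <- (-half:half) / fs_audio
  h <- 2 * fc / fs_audio * ifelse(tt == 0, 1, sin(2 * pi * fc * tt) / (2 * pi * fc * tt))
  h <- h * (0.5 + 0.5 * cos(pi * (-half:half) / half))
  exc_bl <- convolve_fft(exc, h)[(half + 1L):(half + n)]

  # Slow positive random envelope (~2 Hz fluctuations).
  env_n <- max(4L, ceiling(duration * 4))
  env_knots <- runif(env_n, 0.4, 1)
  env <- stats::approx(seq(0, duration, length.out = env_n), env_knots,
                       xout = (seq_len(n) - 1) / fs_audio)$y
  audio <- exc_bl * env

  voiced_rms <- if (any(voiced_mask)) rms(audio[voiced_mask]) else 0
  if (any(!voiced_mask) && voiced_rms > 0) {
    noise <- rnorm(sum(!voiced_mask)) * voiced_rms * 10^(-20 / 20)
    audio[!voiced_mask] <- audio[!voiced_mask] + noise
  }

  f0_track <- rep(NA_real_, n)
  if (length(pulse_times) > 0) {
    vi <- which(voiced_mask)
    nearest <- findInterval((vi - 1) / fs_audio, pulse_times)
    nearest[nearest == 0] <- 1L
    f0_track[vi] <- pulse_f0[nearest]
  }

  structure(list(audio = audio, fs = fs_audio, pulse_times = pulse_times,
                 voiced_mask = voiced_mask, f0_track = f0_track, seed = seed),
            class = "pseudo_speech")
}

#' @export
print.pseudo_speech <- function(x, ...) {
  cat("<pseudo_speech> ", format(length(x$audio) / x$fs), " s @ ", x$fs,
      " Hz, ", length(x$pulse_times), " glottal pulses\n", sep = "")
  invisible(x)
}

#' EEG background-noise specification
#'
#' Describes the additive noise of the synthetic EEG: 1/f^alpha background
#' scaled per trial (so inverse-variance weighting has something to do),
#' plus a power-line sinusoid.
#'
#' @param sd_per_trial Numeric vector of per-trial noise standard deviations
#'   (uV), all > 0. One entry per trial.
#' @param spectral_exponent alpha of the 1/f^alpha background, >= 0.
#' @param line_freq,line_amp Power-line frequency (Hz) and amplitude (uV).
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sd_per_trial, spectral_exponent = 1,
                       line_freq = 60, line_amp = 0.5) {
  # sd 0 is allowed as the noise-free limit used in exactness tests
  stopifnot(all(sd_per_trial >= 0), spectral_exponent >= 0,
            line_freq > 0, line_amp >= 0)
  structure(list(sd_per_trial = sd_per_trial,
                 spectral_exponent = spectral_exponent,
                 line_freq = line_freq, line_amp = line_amp),
            class = "noise_spec")
}

#' Draw log-normal per-trial noise standard deviations
#'
#' @param n_trials Number of trials.
#' @param meanlog,sdlog Log-scale parameters; defaults give sds around 1 uV
#'   varying by roughly a factor of two across trials.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_trials`.
#' @export
draw_trial_sds <- function(n_trials, meanlog = 0, sdlog = 0.35, seed = 1) {
  set.seed(seed)
  rlnorm(n_trials, meanlog, sdlog)
}

#' Synthesize epoched EEG from a known kernel
#'
#' Each trial is the convolution of its regressor with the kernel (kernel
#' lag 0 aligned to time 0), plus 1/f^alpha background noise scaled to the
#' trial's standard deviation and a power-line sinusoid with random phase.
#' Trial edges are handled by front-padding the regressor with its own tail
#' before convolving and trimming, so each trial starts "warm", as a segment
#' cut from a continuous recording would — no cold-start truncation artifact
#' enters the deconvolution. The ground truth is kept in attributes so
#' recovery can be checked downstream.
#'
#' @param kernel A `kernel_truth`.
#' @param regressor A `regressor` object, or a list of them (one per trial).
#'   A single regressor is reused for every trial.
#' @param noise A `noise_spec`; `length(noise$sd_per_trial)` must equal
#'   `n_trials`.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @return An [epoched_eeg] object with attributes `kernel` (the truth) and
#'   `signal` (noise-free trials matrix).
#' @export
synthesize_eeg <- function(kernel, regressor, noise, n_trials, seed = 1) {
  stopifnot(inherits(kernel, "kernel_truth"), inherits(noise, "noise_spec"))
  regs <- if (inherits(regressor, "regressor")) {
    rep(list(regressor), n_trials)
  } else regressor
  if (length(regs) != n_trials) abort("need one regressor (or one per trial)")
  if (length(noise$sd_per_trial) != n_trials) {
    abort("noise$sd_per_trial must have one entry per trial")
  }
  for (r in regs) {
    if (!isTRUE(all.equal(r$fs, kernel$fs))) {
      abort("regressor and kernel sampling rates differ")
    }
  }
  set.seed(seed)
  n <- length(regs[[1]]$samples)
  shift <- round(kernel$lags[1] * kernel$fs) # index offset of lag 0
  trials <- matrix(0, n, n_trials)
  clean <- matrix(0, n, n_trials)
  tvec <- (seq_len(n) - 1) / kernel$fs
  m <- length(kernel$amplitude)
  if (m > n) abort("kernel longer than a trial")
  # kernel placed on the circular time axis at its lags (wrap-padding the
  # regressor with its own tail and trimming is exactly this)
  kz <- numeric(n)
  pos <- ((shift + seq_len(m) - 1) %% n) + 1L
  kz[pos] <- kz[pos] + kernel$amplitude
  KZ <- fft(kz)
  for (j in seq_len(n_trials)) {
    sig <- Re(fft(fft(regs[[j]]$samples) * KZ, inverse = TRUE)) / n
    clean[, j] <- sig
    ns <- if (noise$sd_per_trial[j] > 0) {
      pink_noise(n, noise$spectral_exponent, noise$sd_per_trial[j])
    } else numeric(n)
    if (noise$line_amp > 0) {
      ns <- ns + noise$line_amp *
        sin(2 * pi * noise$line_freq * tvec + runif(1, 0, 2 * pi))
    }
    trials[, j] <- sig + ns
  }
  out <- epoched_eeg(trials, kernel$fs)
  attr(out, "kernel") <- kernel
  attr(out, "signal") <- clean
  out
}
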