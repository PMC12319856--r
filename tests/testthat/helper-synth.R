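# Builders shared across tests. Everything is generated in code at run time.

# white-noise regressors (nonnegative, flat spectrum apart from DC)
white_regressors <- function(n_trials, dur, fs, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    regressor(abs(rnorm(round(dur * fs))), fs, "GP")
  })
}

# A TRF whose broadband signal/noise variance ratio is exact by construction:
# every 15-ms baseline segment is scaled to unit sample variance and the
# signal window to `ratio`, so SNR = 10*log10(ratio - 1).
trf_with_variance_ratio <- function(ratio, fs = 10000, seed = 1) {
  set.seed(seed)
  lags <- seq(round(-1 * fs), round(0.02 * fs)) / fs
  w <- rnorm(length(lags))
  seg <- round(0.015 * fs)
  for (k in 0:32) {
    idx <- (k * seg + 1):((k + 1) * seg)
    w[idx] <- w[idx] / sd(w[idx])
  }
  sig_idx <- which(lags >= -1e-12 & lags < 0.015 - 1e-12)
  w[sig_idx] <- w[sig_idx] / sd(w[sig_idx]) * sqrt(ratio)
  abr_trf(lags, w, fs)
}

# default-condition synthetic subject: kernel, white regressors, 1/f noise
synth_subject <- function(n_trials = 4, dur = 8, fs = 10000, seed = 1,
                          noise_meanlog = 0) {
  k <- make_kernel(lag_range = c(0, 0.25), fs = fs)
  regs <- white_regressors(n_trials, dur, fs, seed)
  sds <- draw_trial_sds(n_trials, meanlog = noise_meanlog, seed = seed + 100)
  eeg <- synthesize_eeg(k, regs, noise_spec(sds), n_trials, seed = seed + 200)
  list(kernel = k, regs = regs, eeg = eeg)
}

nrmse_window <- function(trf, kernel, from = 0, to = 0.015) {
  ti <- trf$lags >= from - 1e-12 & trf$lags <= to + 1e-12
  ki <- kernel$lags >= from - 1e-12 & kernel$lags <= to + 1e-12
  sqrt(mean((trf$weights[ti] - kernel$amplitude[ki])^2)) /
    sqrt(mean(kernel$amplitude[ki]^2))
}
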