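test_that("broadband SNR matches constructed variance ratios within 0.1 dB", {
  for (case in list(c(2, 0), c(11, 10), c(101, 20))) {
    trf <- trf_with_variance_ratio(case[1])
    s <- broadband_snr(trf)
    expect_true(s$defined)
    expect_equal(s$snr_db, case[2], tolerance = 0.1)
  }

  # scale invariance: both variances scale together
  trf <- trf_with_variance_ratio(11)
  scaled <- abr_trf(trf$lags, trf$weights * 7.3, trf$fs)
  expect_equal(broadband_snr(scaled)$snr_db, broadband_snr(trf)$snr_db,
               tolerance = 1e-9)

  # signal below baseline: undefined marker, no exception
  low <- trf_with_variance_ratio(0.5)
  s_low <- broadband_snr(low)
  expect_false(s_low$defined)
  expect_true(is.na(s_low$snr_db))

  # windows must lie inside the lag range
  short <- abr_trf(seq(-100, 100) / 1000, rnorm(201), 1000)
  expect_error(broadband_snr(short), "outside")
})

test_that("per-frequency SNR localises signal and flags undefined bins", {
  fs <- 10000
  lags <- seq(-fs, round(0.02 * fs)) / fs
  set.seed(5)

  # a 500 Hz tone confined to the signal window peaks near 500 Hz
  w <- rnorm(length(lags)) * 0.1
  sig <- lags >= 0 & lags < 0.015
  w[sig] <- w[sig] + 2 * sin(2 * pi * 500 * lags[sig])
  fsnr <- per_frequency_snr(abr_trf(lags, w, fs))
  tbl <- tidy(fsnr)
  best <- tbl$freq[which.max(tbl$snr_db)]
  expect_lt(abs(best - 500), 67)

  # constructed P_SN = 2 P_N everywhere gives 0 dB at every defined bin
  seg <- rnorm(150)
  w2 <- c(rep(seg, length.out = sum(lags < 0)), sqrt(2) * seg,
          numeric(length(lags) - sum(lags < 0) - 150))
  fsnr2 <- per_frequency_snr(abr_trf(lags, w2, fs))
  expect_equal(max(abs(fsnr2$table$snr_db)), 0, tolerance = 1e-6)

  # when the signal window is statistically identical to the baseline, a bin
  # is defined when one ~exponential PSD draw exceeds the 33-segment baseline
  # mean, so the defined fraction sits near exp(-1), well below chance
  # significance and stable across draws
  set.seed(6)
  fracs <- vapply(1:30, function(i) {
    f <- per_frequency_snr(abr_trf(lags, rnorm(length(lags)), fs))
    mean(!is.na(f$table$snr_db))
  }, numeric(1))
  expect_equal(mean(fracs), exp(-1), tolerance = 0.07)
})

test_that("time-to-criterion curves are cumulative proportions", {
  # one subject crossing at 5 min: a 0 -> 1 step
  tbl <- tibble::tibble(subject = 1, duration_min = 1:10,
                        snr_db = c(rep(-5, 4), rep(3, 6)))
  tc <- time_to_criterion(tbl)
  expect_equal(tc$proportion, c(0, 0, 0, 0, rep(1, 6)))

  # a subject never reaching criterion contributes 0 everywhere;
  # undefined SNRs count as not reached
  tbl2 <- dplyr::bind_rows(
    tbl,
    tibble::tibble(subject = 2, duration_min = 1:10, snr_db = rep(-1, 10)),
    tibble::tibble(subject = 3, duration_min = 1:10,
                   snr_db = c(NA, NA, 1, rep(NA, 7))))
  tc2 <- time_to_criterion(tbl2)
  expect_equal(max(tc2$proportion), 2 / 3)
  expect_true(all(diff(tc2$proportion) >= 0))
  # SNR dipping back below criterion does not undo achievement
  expect_equal(tc2$proportion[tc2$duration_min == 10], 2 / 3)

  # mismatched duration grids are rejected
  bad <- dplyr::bind_rows(tbl, tibble::tibble(subject = 9, duration_min = 2:11,
                                              snr_db = rnorm(10)))
  expect_error(time_to_criterion(bad), "grids")
})

test_that("EEG prediction is the windowed-kernel convolution", {
  fs <- 2000
  set.seed(7)
  reg <- regressor(abs(rnorm(fs)), fs, "GP")
  lags <- seq(-round(0.1 * fs), round(0.1 * fs)) / fs

  # unit impulse kernel reproduces the regressor
  w <- numeric(length(lags)); w[lags == 0] <- 1
  imp <- abr_trf(lags, w, fs)
  expect_equal(predict_eeg(imp, reg, c(0, 0.015))[, 1], reg$samples,
               tolerance = 1e-12)

  # all-zero kernel predicts zero
  z <- abr_trf(lags, numeric(length(lags)), fs)
  expect_true(all(predict_eeg(z, reg, c(0, 0.015)) == 0))

  # zero-noise synthetic EEG with kernel supported in [0, 15] ms is
  # reproduced (regressor tail silenced so trial edges hold no response)
  k <- make_kernel(abr_wave_components()[1:3, ], lag_range = c(0, 0.015),
                   fs = fs)
  x <- abs(rnorm(2 * fs)); x[(2 * fs - 50):(2 * fs)] <- 0
  regt <- regressor(x, fs, "GP")
  ee <- synthesize_eeg(k, regt, noise_spec(0, line_amp = 0), 1)
  trf_true <- abr_trf(k$lags, k$amplitude, fs)
  pred <- predict_eeg(trf_true, regt, c(0, 0.015))
  expect_lt(max(abs(pred[, 1] - ee$trials[, 1])) / max(abs(ee$trials[, 1])),
            1e-8)

  expect_error(predict_eeg(imp, reg, c(0, 0.2)), "lag range")
})

test_that("prediction accuracy is the trial-averaged Pearson r", {
  set.seed(8)
  y <- matrix(rnorm(4000), 1000, 4)
  expect_equal(as.numeric(prediction_accuracy(y, y)), 1)
  expect_equal(as.numeric(prediction_accuracy(-y, y)), -1)
  expect_error(prediction_accuracy(y * 0, y), "zero-variance")

  # independent signals decorrelate as 1/sqrt(n)
  n <- 640000
  a <- matrix(rnorm(n * 20), n, 20)
  b <- matrix(rnorm(n * 20), n, 20)
  r <- prediction_accuracy(a, b)
  expect_lt(mean(abs(attr(r, "per_trial"))), 0.005)

  # the 40 Hz high-pass suppresses a shared slow component
  fs <- 1000
  t <- seq_len(2000) / fs
  slow <- sin(2 * pi * 2 * t)
  p <- matrix(slow + rnorm(2000, sd = 0.1))
  q <- matrix(slow + rnorm(2000, sd = 0.1))
  r_bb <- as.numeric(prediction_accuracy(p, q))
  r_hp <- as.numeric(prediction_accuracy(p, q, fs = fs, highpass_40hz = TRUE))
  expect_gt(r_bb, 0.9)
  expect_lt(r_hp, 0.5)
})

test_that("spectral coherence is bounded, signed, and floor-calibrated", {
  fs <- 10000
  set.seed(9)
  y <- matrix(rnorm(4 * fs), fs, 4) # 4 trials x 1 s

  # self-coherence is 1 at every bin, sign flip gives -1
  cs <- spectral_coherence(y, y, fs)
  expect_true(all(abs(Mod(cs$coherence) - 1) < 1e-9))
  cn <- spectral_coherence(y, -y, fs)
  expect_true(all(abs(Re(cn$coherence) + 1) < 1e-9))

  # |C| <= 1 for arbitrary pairings
  cx <- spectral_coherence(y, matrix(rnorm(4 * fs), fs, 4), fs)
  expect_true(all(Mod(cx$coherence) <= 1 + 1e-12))
  expect_equal(cx$freq[2] - cx$freq[1], 5) # 0.2 s slices -> 5 Hz bins

  # independent noise: mean |C| matches the small-sample bias (sqrt(pi)/2)/sqrt(n)
  n_sl <- 400
  big_a <- matrix(rnorm(2000 * n_sl), 2000 * n_sl / 4, 4)
  big_b <- matrix(rnorm(2000 * n_sl), 2000 * n_sl / 4, 4)
  ci <- spectral_coherence(big_a, big_b, fs)
  expect_equal(ci$n_slices, n_sl)
  expected <- (sqrt(pi) / 2) / sqrt(n_sl)
  expect_gt(mean(Mod(ci$coherence)), 0.7 * expected)
  expect_lt(mean(Mod(ci$coherence)), 1.3 * expected)

  expect_error(spectral_coherence(y, y, fs, slice_len = 2), "longer")
})

test_that("the shuffled noise floor sits below matched coherence", {
  fs <- 2000
  set.seed(10)
  k <- make_kernel(abr_wave_components()[1:3, ], lag_range = c(0, 0.015),
                   fs = fs)
  regs <- white_regressors(4, 2, fs, seed = 11)
  ee <- synthesize_eeg(k, regs, noise_spec(rep(0.02, 4), line_amp = 0), 4)
  trf_true <- abr_trf(k$lags, k$amplitude, fs)
  pred <- predict_eeg(trf_true, regs, c(0, 0.015))
  # per-trial demeaning plays the role the preprocessing high-pass plays on
  # real data: without it the DC bin of every pairing is pinned near 1 by the
  # regressors' shared positive mean
  pred <- scale(pred, center = TRUE, scale = FALSE)[, ]
  real <- scale(ee$trials, center = TRUE, scale = FALSE)[, ]
  res <- coherence_noise_floor(pred, real, fs, n_shuffles = 10, seed = 3)
  expect_true(all(Mod(res$coherence) > res$noise_floor))
  expect_true(all(res$noise_floor < 0.5))

  # identical trials: shuffling changes nothing
  same <- matrix(rep(rnorm(400), 3), ncol = 3)
  res2 <- coherence_noise_floor(same + 0, same + 0, fs, slice_len = 0.1,
                                n_shuffles = 5, seed = 4)
  expect_equal(res2$noise_floor, Mod(res2$coherence), tolerance = 1e-12)

  # determinism and the single-trial error
  res3 <- coherence_noise_floor(pred, real, fs, n_shuffles = 10, seed = 3)
  expect_identical(res3$noise_floor, res$noise_floor)
  expect_error(coherence_noise_floor(pred[, 1, drop = FALSE],
                                     ee$trials[, 1, drop = FALSE], fs),
               "two trials")
})

test_that("band means average |C| over closed bands", {
  freq <- seq(0, 200, by = 5)
  co <- structure(list(freq = freq,
                       coherence = complex(modulus = rep(1, length(freq)),
                                           argument = 0),
                       n_slices = 10, slice_len = 0.2, noise_floor = NULL),
                  class = "coherence_result")
  bm <- band_means(co)
  expect_equal(bm$mean_coherence, c(1, 1, 1))
  expect_equal(bm$n_bins[1], 5) # 0,5,10,15,20

  ind <- co
  ind$coherence <- complex(modulus = as.numeric(freq >= 40 & freq <= 60),
                           argument = 0)
  expect_equal(band_means(ind)$mean_coherence, c(0, 1, 0))

  expect_error(band_means(co, bands = list(c(1, 2))), "no bins")
})

test_that("Welch PSD identifies flat, line, and comb spectra", {
  fs <- 10000
  set.seed(12)
  # white noise: flat within Welch variance bounds over 100-4000 Hz
  w <- regressor(abs(rnorm(31 * fs)), fs, "GP")
  pw <- regressor_psd(w)
  expect_gte(pw$n_segments[1], 60)
  band <- pw$psd[pw$freq >= 100 & pw$freq <= 4000]
  expect_lt(max(band) / min(band), 3)

  # a 100 Hz sinusoid peaks at the 100 Hz bin
  t <- seq_len(5 * fs) / fs
  s <- regressor(1 + sin(2 * pi * 100 * t), fs, "GP")
  ps <- regressor_psd(s)
  expect_equal(ps$freq[which.max(ps$psd)], 100)

  # a periodic impulse train has lines at multiples of 1/T
  T_s <- 0.01
  g <- gp_regressor(seq(0, 5 - T_s, by = T_s), 5, fs)
  pg <- regressor_psd(g)
  peaks <- pg$freq[pg$psd > 0.5 * max(pg$psd)]
  expect_true(all(abs((peaks / 100) - round(peaks / 100)) < 0.02))

  expect_error(regressor_psd(regressor(abs(rnorm(100)), fs, "GP")), "segment")
})
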