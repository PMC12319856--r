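test_that("self-deconvolution returns a unit impulse at lag zero", {
  set.seed(1)
  fs <- 10000
  x <- abs(rnorm(2 * fs))
  reg <- regressor(x, fs, "GP")
  trf <- compute_trf(reg, epoched_eeg(matrix(x, ncol = 1), fs),
                     lag_window = c(-0.5, 0.5), eps_scale = 0)
  pk <- which.max(abs(trf$weights))
  expect_equal(trf$lags[pk], 0)
  expect_equal(trf$weights[pk], 1, tolerance = 1e-9)
  off <- sum(trf$weights^2) - trf$weights[pk]^2
  expect_lt(off / trf$weights[pk]^2, 1e-6)
})

test_that("a pure delay appears at the delayed lag (shift theorem)", {
  set.seed(2)
  fs <- 10000
  n <- 2 * fs
  x <- abs(rnorm(n))
  d <- round(0.007 * fs)
  y <- c(x[(n - d + 1):n], x[1:(n - d)])
  trf <- compute_trf(regressor(x, fs, "GP"),
                     epoched_eeg(matrix(y, ncol = 1), fs),
                     lag_window = c(-0.5, 0.5), eps_scale = 0)
  expect_equal(trf$lags[which.max(abs(trf$weights))], 0.007)
})

test_that("deconvolution is linear in the EEG and equivariant to shifts", {
  set.seed(3)
  fs <- 2000
  n <- 2 * fs
  regs <- white_regressors(3, 2, fs, seed = 3)
  y1 <- matrix(rnorm(3 * n), n, 3)
  y2 <- matrix(rnorm(3 * n), n, 3)
  w <- c(0.5, 0.3, 0.2)
  lagw <- c(-0.25, 0.25)
  t1 <- compute_trf(regs, epoched_eeg(y1, fs, weights = w), lagw)
  t2 <- compute_trf(regs, epoched_eeg(y2, fs, weights = w), lagw)
  ts <- compute_trf(regs, epoched_eeg(y1 + y2, fs, weights = w), lagw)
  expect_equal(ts$weights, t1$weights + t2$weights, tolerance = 1e-9)

  # circular delay of every trial shifts the TRF
  d <- 37
  yd <- rbind(y1[(n - d + 1):n, ], y1[1:(n - d), ])
  td <- compute_trf(regs, epoched_eeg(yd, fs, weights = w), lagw)
  i0 <- which(t1$lags == 0)
  keep <- seq_len(length(t1$lags) - d)
  expect_equal(td$weights[keep + d], t1$weights[keep], tolerance = 1e-9)

  # scaling the regressor by c scales the TRF by 1/c
  regs_c <- lapply(regs, function(r) regressor(r$samples * 4, fs, r$kind))
  tc <- compute_trf(regs_c, epoched_eeg(y1, fs, weights = w), lagw)
  expect_equal(tc$weights, t1$weights / 4, tolerance = 1e-9)
})

test_that("equal-variance weighting reduces to the plain average formula", {
  set.seed(4)
  fs <- 2000
  n <- fs
  regs <- white_regressors(3, 1, fs, seed = 5)
  y <- matrix(rnorm(3 * n), n, 3)
  y <- apply(y, 2, function(col) (col - mean(col)) / sd(col))
  trf <- compute_trf(regs, epoched_eeg(y, fs), c(-0.25, 0.25), eps_scale = 0)

  num <- complex(n); den <- numeric(n)
  for (j in 1:3) {
    X <- fft(regs[[j]]$samples); Y <- fft(y[, j])
    num <- num + Conj(X) * Y / 3
    den <- den + Mod(X)^2 / 3
  }
  plain <- Re(fft(num / den, inverse = TRUE)) / n
  idx <- c((n - round(0.25 * fs) + 1):n, 1:(round(0.25 * fs) + 1))
  expect_equal(trf$weights, plain[idx], tolerance = 1e-10)
})

test_that("degenerate regressors and mismatched grids are rejected", {
  fs <- 1000
  y <- matrix(rnorm(2000), 1000, 2)
  zero <- regressor(numeric(1000), fs, "GP")
  ok <- regressor(abs(rnorm(1000)), fs, "GP")
  expect_error(compute_trf(list(ok, zero), epoched_eeg(y, fs), c(-0.1, 0.1)),
               "trial 2")
  expect_error(compute_trf(list(ok), epoched_eeg(y, fs), c(-0.1, 0.1)),
               "one regressor per")
  expect_error(compute_trf(ok, epoched_eeg(y, fs), c(-1, 1)),
               "lag_window")
})

test_that("polarity averaging is the sample-wise mean", {
  lags <- seq(-100, 100) / 1000
  a <- abr_trf(lags, rnorm(201), 1000, "ANM+")
  b <- abr_trf(lags, rnorm(201), 1000, "ANM-")
  avg <- average_polarities(a, b)
  expect_equal(avg$weights, (a$weights + b$weights) / 2)
  expect_equal(avg$regressor_kind, "ANM")
  expect_equal(average_polarities(a, a)$weights, a$weights)
  flip <- abr_trf(lags, -a$weights, 1000, "ANM-")
  expect_true(all(average_polarities(a, flip)$weights == 0))
  c1 <- abr_trf(lags, rep(1, 201), 1000)
  c3 <- abr_trf(lags, rep(3, 201), 1000)
  expect_true(all(average_polarities(c1, c3)$weights == 2))
  short <- abr_trf(lags[1:151], rnorm(151), 1000)
  expect_error(average_polarities(a, short), "grids")
})

test_that("display high-pass reveals fast waves and rejects slow energy", {
  fs <- 10000
  bt <- signal::butter(3, 150 / (fs / 2), type = "high")
  hmag <- function(f) {
    w <- 2 * pi * f / fs
    z <- exp(-1i * w)
    Mod(sum(bt$b * z^(0:3)) / sum(bt$a * z^(0:3)))^2 # squared: zero-phase
  }
  expect_lt(20 * log10(hmag(10)), -60)
  expect_gt(20 * log10(hmag(500)), -1)

  lags <- seq(-fs, fs) / fs
  dc <- abr_trf(lags, rep(2, length(lags)), fs)
  out <- highpass_display(dc)
  expect_lt(max(abs(out$weights)), 1e-6 * 2)

  x500 <- abr_trf(lags, sin(2 * pi * 500 * lags), fs)
  mid <- seq(round(length(lags) * 0.3), round(length(lags) * 0.7))
  amp <- max(abs(highpass_display(x500)$weights[mid]))
  expect_lt(abs(20 * log10(amp)), 1)

  expect_error(highpass_display(x500, cutoff = fs / 2), "Nyquist")
})
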