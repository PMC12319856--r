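#' @useDynLib speechABR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn `%||%`
#' @importFrom stats fft var sd cor median rnorm runif rexp rlnorm pt
NULL

# Fourier-domain resampling: exact rational rate change with a zero-phase
# (linear-phase removed) anti-aliasing brick wall, as used for regressors so
# that no group delay leaks into TRF latencies.
resample_fft <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  n_in <- length(x)
  n_out <- round(n_in * fs_out / fs_in)
  if (n_out < 1) abort("resampled length would be empty")
  X <- fft(x)
  Y <- complex(n_out)
  nk <- min(n_in, n_out)
  half <- (nk + 1) %/% 2 # positive freqs excluding any Nyquist bin
  Y[seq_len(half)] <- X[seq_len(half)]
  if (half > 1) {
    idx_out <- n_out - seq_len(half - 1) + 1L
    idx_in <- n_in - seq_len(half - 1) + 1L
    Y[idx_out] <- X[idx_in]
  }
  # split a shared Nyquist bin symmetrically when one exists
  if (nk %% 2 == 0) {
    nyq <- X[nk %/% 2 + 1L]
    if (n_out > n_in) {
      Y[n_in %/% 2 + 1L] <- nyq / 2
      Y[n_out - n_in %/% 2 + 1L] <- Conj(nyq) / 2
    } else {
      Y[n_out %/% 2 + 1L] <- nyq
    }
  }
  Re(fft(Y, inverse = TRUE)) / n_in
}

# Linear convolution via FFT; returns length(x) + length(k) - 1.
convolve_fft <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
               fft(c(k, numeric(nfft - length(k)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# 1/f^alpha noise by spectral shaping of white Gaussian noise, standardised
# to the requested standard deviation. alpha = 0 gives white noise.
pink_noise <- function(n, alpha = 1, sd = 1) {
  stopifnot(alpha >= 0, sd > 0, n > 1)
  w <- rnorm(n)
  if (alpha == 0) return(w * sd / stats::sd(w))
  W <- fft(w)
  f <- c(1, seq_len(n - 1)) # DC handled below
  f <- pmin(f, n - f + 1) # fold to |frequency|
  shape <- f^(-alpha / 2)
  shape[1] <- 0 # no DC power
  y <- Re(fft(W * shape, inverse = TRUE)) / n
  y * sd / stats::sd(y)
}

# Hann-windowed Welch PSD, one-sided, density scaling (units^2/Hz).
welch_psd <- function(x, fs, seg_len_s = 1, overlap = 0.5) {
  ns <- round(seg_len_s * fs)
  if (length(x) < ns) abort("signal shorter than one Welch segment")
  step <- max(1L, round(ns * (1 - overlap)))
  starts <- seq(1L, length(x) - ns + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(ns) / (ns + 1)) # Hann
  u <- sum(w^2)
  nf <- ns %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    X <- fft((x[s:(s + ns - 1L)] - mean(x[s:(s + ns - 1L)])) * w)
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  p <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when ns is even)
  sc <- rep(2, nf); sc[1] <- 1
  if (ns %% 2 == 0) sc[nf] <- 1
  tibble::tibble(freq = (seq_len(nf) - 1) * fs / ns,
                 psd = p * sc,
                 n_segments = length(starts))
}

# First Slepian (DPSS) taper by the exact symmetric tridiagonal eigenproblem;
# W is the half-bandwidth as a fraction of the sampling rate. Unit energy,
# positive mean.
dpss_first <- function(n, w) {
  stopifnot(n > 2, w > 0, w < 0.5)
  t <- seq_len(n) - 1
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  e <- t[-1] * (n - t[-1]) / 2
  m <- diag(d)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- e
  m[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- e
  v <- eigen(m, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# Single-taper (first Slepian) PSD of a short segment; `bandwidth_hz` is the
# full spectral bandwidth of the taper. One-sided density scaling.
taper_psd <- function(x, fs, bandwidth_hz = 67) {
  n <- length(x)
  w <- (bandwidth_hz / 2) / fs
  tap <- dpss_first(n, w)
  nf <- n %/% 2 + 1L
  X <- fft(x * tap)
  p <- Mod(X[seq_len(nf)])^2 / fs
  sc <- rep(2, nf); sc[1] <- 1
  if (n %% 2 == 0) sc[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / n, psd = p * sc)
}

# RBJ biquad notch coefficients at f0 with quality factor q.
notch_biquad <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

rms <- function(x) sqrt(mean(x^2))

check_finite <- function(x, what) {
  if (!all(is.finite(x))) abort(paste0(what, " contains non-finite samples"))
  invisible(x)
}
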