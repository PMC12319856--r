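# Bundled simplified auditory periphery ("ANM-lite").
#
# Stage 1: 4th-order gammatone bandpass at the CF (Slaney's ERB all-pole
#          design as a cascade of four second-order sections, numerically
#          normalised to unity gain at CF).
# Stage 2: inner-hair-cell transduction: half-wave rectification followed by
#          a first-order 3 kHz low-pass (membrane smoothing).
# Stage 3: three-store transmitter-depletion adaptation (free pool, synaptic
#          cleft, reprocessing store) with saturating calcium-like
#          permeability, integrated at the model rate in C++. Produces onset
#          emphasis, post-onset adaptation, compressive rate-level growth and
#          a nonzero spontaneous rate.
#
# No numeric parity with detailed cat/human periphery models is claimed; the
# stage structure keeps the nonlinearities (rectification, saturation,
# adaptation) that matter for deconvolution regressors.

# ERB of the auditory filter at centre frequency cf (Glasberg & Moore).
erb_bandwidth <- function(cf) 24.7 * (4.37 * cf / 1000 + 1)

# Second-order-section coefficients of the Slaney gammatone at cf.
# Returns list of four sections, each list(b, a), overall unity gain at cf.
gammatone_sos <- function(cf, fs) {
  T <- 1 / fs
  B <- 1.019 * 2 * pi * erb_bandwidth(cf)
  wc <- 2 * pi * cf * T
  e <- exp(-B * T)
  a <- c(1, -2 * cos(wc) * e, e^2)
  s1 <- sqrt(3 + 2^1.5); s2 <- sqrt(3 - 2^1.5)
  b1 <- c(T, -(2 * T * cos(wc) * e + 2 * s1 * T * sin(wc) * e) / 2, 0)
  b2 <- c(T, -(2 * T * cos(wc) * e - 2 * s1 * T * sin(wc) * e) / 2, 0)
  b3 <- c(T, -(2 * T * cos(wc) * e + 2 * s2 * T * sin(wc) * e) / 2, 0)
  b4 <- c(T, -(2 * T * cos(wc) * e - 2 * s2 * T * sin(wc) * e) / 2, 0)
  sos <- list(list(b = b1, a = a), list(b = b2, a = a),
              list(b = b3, a = a), list(b = b4, a = a))
  # normalise the cascade numerically to |H(cf)| = 1
  z <- exp(-1i * wc)
  h <- 1 + 0i
  for (s in sos) {
    h <- h * (s$b[1] + s$b[2] * z + s$b[3] * z^2) /
      (s$a[1] + s$a[2] * z + s$a[3] * z^2)
  }
  sos[[1]]$b <- sos[[1]]$b / Mod(h)
  sos
}

gammatone_filter <- function(x, fs, cf) {
  for (s in gammatone_sos(cf, fs)) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
  }
  x
}

# Adaptation-stage parameters (three-store transmitter model, canonical
# hair-cell synapse constants). Input is scaled IHC potential (a.u.).
anm_lite_params <- function() {
  list(A = 5, B = 300, g = 2000, y = 5.05, l = 2500, r = 6580,
       x = 66.31, M = 1, h = 50000, input_gain = 1e4)
}

# Steady-state (spontaneous) firing rate of the adaptation stage per fiber,
# used when subtracting the resting baseline. Vectorised over cfs (the rate
# is CF-independent in this model).
anm_lite_spont_rate <- function(cfs) {
  p <- anm_lite_params()
  k0 <- p$g * p$A / (p$A + p$B)
  q <- p$y * p$M / (p$y + k0 * p$l / (p$l + p$r))
  c0 <- k0 * q / (p$l + p$r)
  rep(p$h * c0, length(cfs))
}

#' Single-fiber response of the bundled periphery
#'
#' Instantaneous firing rate (spikes/s) of a high-spontaneous-rate fiber at
#' one characteristic frequency, for a pascal-scaled stimulus at the model
#' sampling rate. Used internally by [anm_regressor()]; exposed for
#' inspection and testing of the periphery stages.
#'
#' @param audio_pa Stimulus in pascals at `fs`.
#' @param fs Model sampling rate, Hz (100 kHz by convention).
#' @param cf Characteristic frequency, Hz.
#' @return Numeric vector of firing rates, spikes/s.
#' @export
anm_lite <- function(audio_pa, fs, cf) {
  p <- anm_lite_params()
  bm <- gammatone_filter(audio_pa, fs, cf)
  # IHC: rectify then 3 kHz first-order low-pass (causal, like the membrane)
  v <- pmax(bm, 0)
  lp <- signal::butter(1, min(3000 / (fs / 2), 0.99), type = "low")
  v <- as.numeric(signal::filter(lp$b, lp$a, v))
  v <- pmax(v, 0) * p$input_gain
  meddis_synapse(v, 1 / fs, p$A, p$B, p$g, p$y, p$l, p$r, p$x, p$M, p$h)
}
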