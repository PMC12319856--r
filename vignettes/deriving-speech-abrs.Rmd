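---
title: "Deriving auditory brainstem responses from continuous speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving auditory brainstem responses from continuous speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The encoding model

speechABR treats the auditory brainstem response (ABR) to continuous speech
as the impulse response of a linear system. A stimulus feature — the
*regressor* $x$ — drives single-channel EEG $y$ through convolution with an
unknown kernel, the temporal response function (TRF):

$$ y_n(t) = (x_n \ast \mathrm{response})(t) + \text{noise}, $$

for trials $n = 1 \dots N$. The kernel is estimated in the frequency domain,

$$ \widehat{\mathrm{response}} = \mathcal{F}^{-1}\!\left\{
   \frac{\sum_n b_n X_n^* Y_n}{\tfrac{1}{N}\sum_n X_n^* X_n + \epsilon}
   \right\}, $$

with $X_n, Y_n$ the trial FFTs, $^*$ complex conjugation, and $b_n$
normalised inverse-variance trial weights
$b_n = (1/\sigma_n^2)\,/\,\sum_m (1/\sigma_m^2)$, which down-weight noisy
trials. Because the FFT length equals the trial length the estimator is
circular; negative lags are read from the end of the lag axis, which is what
makes the pre-stimulus baseline windows used by the SNR metrics well defined.

Assumptions worth keeping in mind: the response is linear and
time-invariant within a trial; trial noise is stationary enough that one
variance per trial is a sensible weight; and the regressor actually carries
the temporal structure that drives the brainstem. The third assumption is
the interesting one — it is why the package implements three regressors.

## The three regressors

* **HWR** — the half-wave rectified stimulus waveform, resampled to the EEG
  rate (10 kHz). Computed for both stimulus polarities (positive part, and
  positive part of the inverted waveform); the two TRFs are averaged.
* **GP** — a train of unit impulses at the glottal pulse times. Pulse times
  are an input (one plain-text file of seconds per trial); the package never
  extracts them from audio. Impulses land on the nearest EEG sample (ties to
  even) and coincident pulses accumulate.
* **ANM** — the instantaneous firing rate of a simplified auditory-nerve
  periphery, summed across characteristic frequencies (CFs) of
  high-spontaneous-rate fibers and resampled to 10 kHz, again for both
  polarities. The stimulus is upsampled to the 100 kHz model rate and scaled
  to pascals at 65 dB SPL (RMS re 20 µPa) before entering the model.

### The bundled periphery ("ANM-lite")

The bundled backend is deliberately simple: a fourth-order gammatone
filterbank (Slaney's ERB design, unity gain at CF, 125 Hz–16 kHz at 1/6
octave = 43 CFs by default), an inner-hair-cell stage (half-wave
rectification plus a first-order 3 kHz low-pass), and a three-store
transmitter-depletion synapse (free pool, cleft, reprocessing store) with a
saturating permeability, integrated at the model rate in C++. This keeps the
nonlinearities that matter for deconvolution regressors — rectification,
compressive rate-level growth, onset emphasis and adaptation, and a nonzero
spontaneous rate (retained by default; `subtract_spont` removes it) — while
making no claim of numeric parity with detailed research-grade periphery
models. One consequence of transmitter depletion worth knowing: the
*sustained* rate saturates and can decline slightly above ~60 dB SPL while
the *onset* response keeps growing; the level-monotonicity tests therefore
look at the onset. For benchmark work against a full periphery model, pass a
function `(audio_pa, fs, cfs) -> rate matrix` as
`periphery_config(backend = ...)`.

## Preprocessing and weighting

Raw EEG is high-passed at 1 Hz (first order, causal) and notch-filtered at
60 Hz and its first three odd harmonics (biquad notches, Q = 30 — the
quality factor is a package choice; nothing hinges on it as long as the
notch is narrow). A zero-phase variant exists behind `zero_phase = TRUE`.
Trials are cut at onsets, and each trial's weight is computed from the
sample variance of the whole filtered trial. Synthetic and ingested EEG go
through the same code path.

## Evaluation suite

* **Broadband SNR** — signal-plus-noise variance over lags 0–15 ms versus
  the mean variance of the 33 non-overlapping 15-ms segments in the
  −1000…−500 ms baseline: $10\log_{10}((\sigma^2_{S+N}-\sigma^2_N)/\sigma^2_N)$.
  When the window variance does not exceed the baseline the value is
  *undefined* and reported as an `NA` marker, never dropped silently and
  never an exception.
* **Per-frequency SNR** — same construction per frequency bin with
  single-taper PSDs (first Slepian taper, 67 Hz full bandwidth; for a 15-ms
  segment that is a time-half-bandwidth of ≈ 0.5, so exactly one usable
  taper). Note one statistical subtlety: because the baseline PSD is a mean
  over 33 segments while the signal PSD is a single draw, a bin whose signal
  is statistically identical to the baseline is defined with probability
  ≈ e^{-1}, not 1/2.
* **Time-to-criterion** — broadband SNR recomputed on nested prefixes of the
  trial sequence, then the cumulative proportion of subjects at ≥ 0 dB per
  recording duration.
* **Prediction accuracy** — the TRF restricted to a kernel window
  ([0, 15] ms subcortical, [0, 200] ms full) is convolved with each trial's
  regressor and correlated with the recorded trial (Pearson r per trial,
  unweighted mean across trials). An optional 40 Hz first-order causal
  high-pass de-emphasises slow cortical activity before correlating.
* **Spectral coherence** — complex coherence per 5 Hz bin from 0.2-s slices
  pooled across trials, with a noise floor from re-paired (never matched)
  trials: per-bin median magnitude over shuffles. Band summaries default to
  the 0–20, 40–60 and 80–120 Hz bands; the wider 0–25 / 25–85 / 85–135 Hz
  partition can be passed to `band_means()` instead.
* **Statistics** — one-way repeated-measures ANOVA (no sphericity
  correction by default, Greenhouse–Geisser behind a flag), pairwise paired
  t-tests, Holm–Bonferroni adjustment within each (condition, metric)
  family. Mixed-effects models are out of scope; use lme4 on the tidy
  metric table if needed.

## The synthetic-data generator

`make_pseudo_speech()` emulates only the statistics the regressors consume:
alternating voiced/unvoiced spans (exponential lengths, expected voiced
fraction as requested), glottal pulses at jittered 1/f0 intervals inside
voiced spans, a band-limited excitation shaped by a slow positive envelope,
and unvoiced noise at −20 dB relative to voiced RMS. It is not speech: no
formants, no intelligibility, a single synthetic "talker".

`make_kernel()` builds the ground-truth response as Gaussian bumps. Defaults
place wave I at 3.2 ms and wave V at 7.2 ms — the latencies reported for
speech-derived ABRs — with widths of 0.25 ms (waves I/III) and 0.5 ms
(wave V). Wave III has no published latency for this paradigm, so the
default (5.2 ms) interpolates the click-ABR I–III–V progression; a slow
"cortical" bump (100 ms latency, 20 ms width) makes the full-kernel
prediction window meaningful. Amplitudes (0.15–0.8 µV per regressor unit)
sit in the sub-microvolt range typical of ABRs.

`synthesize_eeg()` adds 1/f^α background noise (α = 1 by default — EEG-like,
though the real noise spectrum is not characterised in this paradigm, so α
is a package choice) scaled to a per-trial standard deviation (log-normal
draws by default, so inverse-variance weighting has real work to do) plus a
60 Hz line sinusoid to exercise the notch filters. Trial edges are handled
by treating the stimulus as continuous: the regressor is wrap-padded with
its own tail before convolving and trimming, so each trial starts "warm" the
way a segment cut from a continuous recording does, and the generator
matches the periodic model the circular deconvolution assumes. What passing
tests on this generator do **not** show: robustness to artifacts,
non-stationary noise, electrode drift, or regressor model mismatch beyond
what the three regressors themselves embody.

## Numerical choices

* Regularisation: the deconvolution denominator gets a ridge
  $\epsilon = 10^{-6} \times$ its mean magnitude, because sparse regressors
  (pulse trains) have spectral nulls; `eps_scale = 0` restores the bare
  estimator (used when comparing against the least-squares oracle).
* Resampling is Fourier-domain and zero-phase, so regressor construction
  adds no group delay to TRF latencies. Rectified-then-resampled signals can
  ring slightly negative; those samples are clamped to zero.
* The display high-pass (150 Hz, third-order Butterworth) is applied
  forward-backward with odd-reflection padding, so it is zero-phase and free
  of edge transients.
* Degenerate inputs are errors, not guesses: zero-power regressors, kernels
  longer than a trial, zero-variance trials, windows outside the lag range,
  single-trial noise floors. Two deliberate exceptions follow the metric
  definitions: undefined SNR is a marker, and a paired t of identical
  vectors is (t = 0, p = 1) while a constant nonzero difference is an error.

## Problem sizes used in the shipped runs

The test suite runs in well under a minute except for the full-scale kernel
recovery check (10 trials × 64 s × 10 kHz). The acceptance script runs a
cohort of 6 synthetic subjects × 4 trials × 6 s with all three regressors —
the periphery there uses a 1/2-octave CF grid (15 CFs) to keep the run to a
few minutes; the method is unchanged by CF count — plus the 10 × 64 s
kernel-recovery benchmark at the generator's default ~1 µV trial noise.
These sizes are the package's chosen demonstration scale; every routine
accepts the full-scale inputs.

## Known limitations

* The bundled periphery is a caricature: no middle ear, no level-dependent
  filter bandwidths, HSR fibers only. Its purpose is a regressor with the
  right nonlinearities, not a model of the cat or human auditory nerve.
* Single-channel analysis only; no artifact rejection or re-referencing.
* The GP regressor presumes pulse times exist (peaky or voiced speech);
  it degrades gracefully but meaninglessly on arbitrary audio.
* EEG ingestion is float32-plus-JSON-sidecar (and WAV for stimuli); EDF is
  not read directly — convert upstream.
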