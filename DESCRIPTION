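Package: speechABR
Title: Auditory Brainstem Responses from Continuous Speech by Weighted
    Frequency-Domain Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the auditory brainstem response (ABR) from EEG recorded
    during continuous speech listening, as the temporal response function of a
    linear encoding model estimated by inverse-variance-weighted frequency-domain
    deconvolution. Implements three stimulus regressors (half-wave rectified
    audio, glottal pulse train, and a simplified auditory-nerve-model firing
    rate with gammatone filtering and transmitter-depletion adaptation), EEG
    preprocessing and trial weighting, and a complete evaluation suite:
    broadband and per-frequency signal-to-noise ratio, time-to-criterion
    curves, EEG prediction accuracy, spectral coherence with a shuffled noise
    floor, and repeated-measures statistics with Holm-Bonferroni correction.
    A synthetic-data generator produces pseudo-speech stimuli, ground-truth
    ABR kernels and realistic EEG so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
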