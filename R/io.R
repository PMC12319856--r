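# File ingestion and export: mono WAV (PCM16 / IEEE float32), plain-text
# pulse times, and float32 EEG with a JSON sidecar. Minimal by design — these
# are the interchange formats of the pipeline, not a general audio library.

#' Read a mono WAV file
#'
#' Supports PCM 16-bit and IEEE float32; multichannel files are averaged to
#' mono. Samples are returned in `(-1, 1)` for PCM.
#'
#' @param path Path to a `.wav` file.
#' @return List with `audio` (numeric vector) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") abort("not a RIFF/WAV file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") abort("not a WAV file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little",
                       signed = FALSE))
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) abort("malformed WAV: missing fmt or data chunk")
  x <- if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data, "integer", length(data) / 2, 2, endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data, "numeric", length(data) / 4, 4, endian = "little")
  } else {
    abort("only PCM16 and float32 WAV are supported")
  }
  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  list(audio = x, fs = fmt$fs)
}

#' Write a mono WAV file
#'
#' @param audio Numeric vector; clipped to the unit range for PCM16.
#' @param fs Sampling rate, Hz.
#' @param path Output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, fs, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- length(audio) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(8L * bytes_per, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(pmax(pmin(audio, 1), -1) * 32767)), con, 2,
             endian = "little")
  } else {
    writeBin(audio, con, 4, endian = "little")
  }
  invisible(path)
}

#' Read/write glottal pulse times
#'
#' Plain text, one time in seconds per line.
#'
#' @param path File path.
#' @return `read_pulse_times`: sorted numeric vector of seconds.
#' @export
read_pulse_times <- function(path) {
  sort(as.numeric(readLines(path)))
}

#' @rdname read_pulse_times
#' @param times Numeric vector of seconds.
#' @export
write_pulse_times <- function(times, path) {
  writeLines(format(times, digits = 12, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Write epoched EEG as float32 binary plus JSON sidecar
#'
#' Trials are concatenated column-wise into little-endian float32; the
#' sidecar records `fs`, `n_trials`, `trial_len_s`, `units` and trial onsets.
#'
#' @param eeg An [epoched_eeg].
#' @param path Binary output path (sidecar is `paste0(path, ".json")`).
#' @param units Unit string stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_eeg_bin <- function(eeg, path, units = "uV") {
  stopifnot(inherits(eeg, "epoched_eeg"))
  con <- file(path, "wb")
  writeBin(as.vector(eeg$trials), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(fs = eeg$fs, n_trials = eeg$n_trials, trial_len_s = eeg$trial_len,
         units = units,
         onsets_s = seq(0, by = eeg$trial_len, length.out = eeg$n_trials)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read float32 EEG with JSON sidecar
#'
#' @param path Binary path written by [write_eeg_bin()] (or compatible).
#' @return An [epoched_eeg].
#' @export
read_eeg_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- round(meta$fs * meta$trial_len_s) * meta$n_trials
  con <- file(path, "rb")
  x <- readBin(con, "numeric", n, size = 4, endian = "little")
  close(con)
  epoched_eeg(matrix(x, ncol = meta$n_trials), meta$fs)
}
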