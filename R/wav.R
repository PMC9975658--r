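#' Audio recordings
#'
#' An `audio_recording` is a lightweight container for a mono waveform:
#' a numeric vector of samples plus its sampling rate in Hz. All analysis
#' functions in the package operate on mono audio; stereo input is averaged
#' down with a warning.
#'
#' @param samples Numeric vector (or a samples x channels matrix) of
#'   amplitudes. Must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param source_id Optional label carried through to derived envelopes.
#'
#' @return An object of class `audio_recording` with elements `samples`,
#'   `sample_rate` and `source_id`.
#' @export
#' @examples
#' a <- audio_recording(sin(2 * pi * 100 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(a)
audio_recording <- function(samples, sample_rate, source_id = NULL) {
  check_number(sample_rate, "sample_rate", lower = 1e-9)
  if (is.matrix(samples)) {
    if (ncol(samples) > 1L) {
      rlang::warn("Averaging multi-channel audio to mono.")
    }
    samples <- rowMeans(samples)
  }
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop_invalid_input("Audio samples must be finite numeric values.")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         source_id = source_id),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate, duration(x)))
  invisible(x)
}

#' Duration of an audio recording or envelope, in seconds
#' @param x An `audio_recording` or `envelope_series`.
#' @return Duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.audio_recording <- function(x) length(x$samples) / x$sample_rate

#' Read and write mono/stereo WAV files
#'
#' Minimal RIFF/WAVE support covering the formats the package writes:
#' 16-bit PCM and 32-bit IEEE float. Multi-channel files are averaged to
#' mono on read.
#'
#' @param path Path to a `.wav` file.
#' @return `read_wav()` returns an [audio_recording()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid_input("Not a RIFF/WAVE file.")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_invalid_input("Not a RIFF/WAVE file.")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) {
      stop_invalid_input("WAV file has no data chunk.")
    }
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_invalid_input("WAV data chunk precedes fmt.")
      n <- size %/% (fmt$bits %/% 8)
      x <- if (fmt$format == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n, size = 2, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop_invalid_input(sprintf(
          "Unsupported WAV encoding (format %d, %d bits).",
          fmt$format, fmt$bits))
      }
      if (fmt$channels > 1L) {
        x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
        rlang::warn("Averaging multi-channel WAV to mono.")
      }
      return(audio_recording(x, fmt$sample_rate, source_id = basename(path)))
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
}

#' @rdname read_wav
#' @param audio An [audio_recording()] (or bare numeric vector with
#'   `sample_rate` supplied).
#' @param sample_rate Sampling rate in Hz, required when `audio` is a bare
#'   vector.
#' @param bits Either 16 (PCM) or 32 (IEEE float).
#' @return `write_wav()` invisibly returns `path`.
#' @export
write_wav <- function(audio, path, sample_rate = NULL, bits = 16) {
  if (!inherits(audio, "audio_recording")) {
    audio <- audio_recording(audio, sample_rate)
  }
  x <- audio$samples
  fs <- as.integer(round(audio$sample_rate))
  bytes <- bits %/% 8
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt_code <- if (bits == 16) 1L else 3L
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32768)))),
             con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
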