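#' Amplitude envelope and narrowband phase containers
#'
#' `envelope_series` holds a uniformly sampled, nonnegative amplitude
#' envelope; `phase_series` holds the instantaneous narrowband phase of an
#' envelope, in radians in (-pi, pi], together with the band it was
#' extracted from. These are the intermediate objects between raw audio and
#' phase-locking analysis.
#'
#' @param values Nonnegative numeric vector of envelope amplitudes.
#' @param sample_rate Sampling rate in Hz.
#' @param kind Provenance of the envelope: `"cochlear"`, `"hilbert"`, or
#'   `"synthetic"`.
#' @param source_id Optional label.
#' @return An `envelope_series` (resp. `phase_series`) object.
#' @export
envelope_series <- function(values, sample_rate,
                            kind = c("hilbert", "cochlear", "synthetic"),
                            source_id = NULL) {
  kind <- match.arg(kind)
  check_number(sample_rate, "sample_rate", lower = 1e-9)
  if (!is.numeric(values) || anyNA(values)) {
    stop_invalid_input("Envelope values must be numeric and non-missing.")
  }
  if (any(values < 0)) {
    stop_invalid_input("Envelope values must be nonnegative.")
  }
  structure(
    list(values = as.numeric(values), sample_rate = sample_rate,
         kind = kind, source_id = source_id),
    class = "envelope_series"
  )
}

#' @export
duration.envelope_series <- function(x) length(x$values) / x$sample_rate

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series (%s): %d samples @ %g Hz>\n",
              x$kind, length(x$values), x$sample_rate))
  invisible(x)
}

#' @rdname envelope_series
#' @param phase Numeric vector of phases in radians.
#' @param band Length-2 numeric, the (low, high) passband in Hz.
#' @export
phase_series <- function(phase, sample_rate, band, source_id = NULL) {
  check_number(sample_rate, "sample_rate", lower = 1e-9)
  if (length(phase) < 2L) {
    stop_invalid_input("A phase series needs at least 2 samples.")
  }
  if (!is.numeric(band) || length(band) != 2L || band[1] >= band[2]) {
    stop_invalid("`band` must be (low, high) with low < high.")
  }
  phase <- wrap_phase(as.numeric(phase))
  structure(
    list(phase = phase, sample_rate = sample_rate, band = band,
         source_id = source_id),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series: %d samples @ %g Hz, band %.2f-%.2f Hz>\n",
              length(x$phase), x$sample_rate, x$band[1], x$band[2]))
  invisible(x)
}

# Wrap radians into (-pi, pi].
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' @exportS3Method generics::tidy
tidy.envelope_series <- function(x, ...) {
  tibble::tibble(
    time = (seq_along(x$values) - 1) / x$sample_rate,
    value = x$values
  )
}

#' @exportS3Method generics::tidy
tidy.phase_series <- function(x, ...) {
  tibble::tibble(
    time = (seq_along(x$phase) - 1) / x$sample_rate,
    phase = x$phase
  )
}

# Analytic signal via the FFT method: zero negative frequencies, double
# positive ones. Exact for finite discrete signals up to circularity.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop_invalid_input("Need at least 2 samples.")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Broadband Hilbert envelope
#'
#' The amplitude envelope as the magnitude of the analytic signal,
#' \eqn{|x(t) + i\,\mathcal{H}x(t)|}. This is the envelope used for
#' produced-speech recordings.
#'
#' @param audio An [audio_recording()].
#' @return An [envelope_series()] of kind `"hilbert"` at the audio rate.
#' @export
#' @examples
#' fs <- 1000
#' t <- seq(0, 1, by = 1 / fs)
#' a <- audio_recording(0.7 * sin(2 * pi * 100 * t), fs)
#' env <- hilbert_envelope(a)
#' round(median(env$values), 3)
hilbert_envelope <- function(audio) {
  if (!inherits(audio, "audio_recording")) {
    stop_invalid_input("`audio` must be an audio_recording.")
  }
  if (length(audio$samples) < 2L) {
    stop_invalid_input("Audio must contain at least 2 samples.")
  }
  envelope_series(Mod(analytic_signal(audio$samples)), audio$sample_rate,
                  kind = "hilbert", source_id = audio$source_id)
}

# ERB-rate scale (Glasberg & Moore) and gammatone kernels.
hz_to_erb_rate <- function(f) 21.4 * log10(0.00437 * f + 1)
erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# 4th-order gammatone FIR kernel at centre frequency fc, peak-normalized in
# the frequency domain; returns the kernel and its envelope-peak delay.
gammatone_kernel <- function(fc, fs) {
  b <- 1.019 * erb_bandwidth(fc)
  t_max <- max(12 / (2 * pi * b), 0.004)
  t <- seq(0, t_max, by = 1 / fs)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  gain <- max(Mod(fft(c(g, numeric(length(g))))))
  list(kernel = g / gain, delay = which.max(t^3 * exp(-2 * pi * b * t)) - 1L)
}

#' Cochlear amplitude envelope via a gammatone filterbank
#'
#' Emulates cochlear envelope extraction: the audio is passed through a bank
#' of `n_channels` 4th-order gammatone filters with centre frequencies
#' spaced uniformly on the ERB-rate scale across `band` (default 180--7246
#' Hz), each channel's Hilbert envelope is taken, channel outputs are
#' aligned for filter delay and averaged. Used for the syllable-train
#' stimulus.
#'
#' @param audio An [audio_recording()] (mono).
#' @param n_channels Number of gammatone channels (default 30).
#' @param band Length-2 numeric, lowest and highest centre frequency in Hz.
#' @return An [envelope_series()] of kind `"cochlear"` at the audio rate.
#' @export
cochlear_envelope <- function(audio, n_channels = 30,
                              band = c(180, 7246)) {
  if (!inherits(audio, "audio_recording")) {
    stop_invalid_input("`audio` must be an audio_recording.")
  }
  check_count(n_channels, "n_channels", lower = 1L)
  nyq <- audio$sample_rate / 2
  if (band[2] >= nyq) {
    stop_invalid(sprintf(
      "Channel band (%g-%g Hz) must lie below the Nyquist frequency %g Hz.",
      band[1], band[2], nyq))
  }
  x <- audio$samples
  n <- length(x)
  cfs <- erb_rate_to_hz(seq(hz_to_erb_rate(band[1]), hz_to_erb_rate(band[2]),
                            length.out = n_channels))
  kernels <- lapply(cfs, gammatone_kernel, fs = audio$sample_rate)
  nfft <- 2^ceiling(log2(n + max(lengths(lapply(kernels, `[[`, "kernel")))))
  fx <- fft(c(x, numeric(nfft - n)))
  acc <- numeric(n)
  for (k in kernels) {
    fk <- fft(c(k$kernel, numeric(nfft - length(k$kernel))))
    y <- Re(fft(fx * fk, inverse = TRUE)) / nfft
    # compensate the channel's envelope delay so channels sum coherently
    y <- y[seq.int(1L + k$delay, length.out = n)]
    acc <- acc + Mod(analytic_signal(y))
  }
  envelope_series(acc / length(kernels), audio$sample_rate,
                  kind = "cochlear", source_id = audio$source_id)
}

# Fourier-method resampling of a real signal to m samples: truncate the
# spectrum (ideal anti-alias filter for band-limited input) and invert.
fourier_resample <- function(x, m) {
  n <- length(x)
  X <- fft(x)
  Y <- complex(m)
  half <- min(n, m)
  keep <- floor(half / 2)
  Y[1:(keep + 1)] <- X[1:(keep + 1)]
  if (keep >= 1) Y[(m - keep + 1):m] <- X[(n - keep + 1):n]
  if (half %% 2 == 0) {
    # split the shared Nyquist bin to keep the result real-symmetric
    nyq <- X[keep + 1]
    if (m < n) {
      Y[keep + 1] <- nyq + X[n - keep + 1]
    } else if (m > n) {
      Y[keep + 1] <- nyq / 2
      Y[m - keep + 1] <- nyq / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Downsample an envelope
#'
#' Resamples an envelope to a lower rate using Fourier-method resampling,
#' which applies an ideal anti-aliasing filter before decimation. Analysis
#' envelopes are taken to 100 Hz before phase extraction, so only
#' downsampling is supported.
#'
#' @param env An [envelope_series()].
#' @param target_hz Target sampling rate in Hz, strictly below the current
#'   rate.
#' @return An [envelope_series()] at `target_hz`. Tiny negative excursions
#'   introduced by the ideal filter are clipped to zero.
#' @export
resample_envelope <- function(env, target_hz) {
  if (!inherits(env, "envelope_series")) {
    stop_invalid_input("`env` must be an envelope_series.")
  }
  check_number(target_hz, "target_hz", lower = 1e-9)
  if (target_hz >= env$sample_rate) {
    stop_invalid(sprintf(
      "Upsampling requested (%g -> %g Hz); only downsampling is supported.",
      env$sample_rate, target_hz))
  }
  m <- max(2L, round(length(env$values) * target_hz / env$sample_rate))
  y <- fourier_resample(env$values, m)
  envelope_series(pmax(y, 0), target_hz, kind = env$kind,
                  source_id = env$source_id)
}

# Squared-magnitude response of an order-n Butterworth bandpass, evaluated
# on the FFT frequency grid. Applying it in the frequency domain is the
# exact zero-phase (forward-backward) version of the filter.
butter_bandpass_gain2 <- function(freqs, low, high, order = 4) {
  bw <- high - low
  q <- ifelse(freqs == 0, Inf,
              (freqs^2 - low * high) / (pmax(freqs, .Machine$double.eps) * bw))
  1 / (1 + q^(2 * order))
}

zero_phase_bandpass <- function(x, fs, low, high, order = 4) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs) # two-sided grid folded to |f|
  Re(fft(fft(x) * butter_bandpass_gain2(freqs, low, high, order),
         inverse = TRUE)) / n
}

#' Narrowband phase of an envelope
#'
#' Band-pass filters the envelope in the syllabic (theta) range with a
#' zero-phase 4th-order Butterworth response and extracts the instantaneous
#' phase of the analytic signal. The first and last `trim_s` seconds are
#' dropped by default to discard filter and Hilbert edge effects.
#'
#' @param env An [envelope_series()].
#' @param band Passband in Hz; default `c(3.5, 5.5)`, bracketing the
#'   syllable rates of the synchronization stimulus.
#' @param trim_s Seconds to trim from each end of the resulting phase series
#'   (default 1; set 0 to keep everything).
#' @param order Butterworth order (default 4).
#' @return A [phase_series()].
#' @export
bandpass_phase <- function(env, band = c(3.5, 5.5), trim_s = 1, order = 4) {
  if (!inherits(env, "envelope_series")) {
    stop_invalid_input("`env` must be an envelope_series.")
  }
  if (!is.numeric(band) || length(band) != 2L || band[1] <= 0 ||
      band[1] >= band[2]) {
    stop_invalid("`band` must be (low, high) Hz with 0 < low < high.")
  }
  if (band[2] >= env$sample_rate / 2) {
    stop_invalid(sprintf(
      "Band edge %g Hz is not below the Nyquist frequency %g Hz.",
      band[2], env$sample_rate / 2))
  }
  check_number(trim_s, "trim_s", lower = 0)
  y <- zero_phase_bandpass(env$values, env$sample_rate, band[1], band[2],
                           order = order)
  ph <- Arg(analytic_signal(y))
  k <- floor(trim_s * env$sample_rate)
  if (2 * k >= length(ph) - 1) {
    stop_invalid_input("Envelope too short for the requested edge trim.")
  }
  if (k > 0) ph <- ph[(k + 1):(length(ph) - k)]
  phase_series(ph, env$sample_rate, band, source_id = env$source_id)
}
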