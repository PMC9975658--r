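#' Build a syllable-train stimulus
#'
#' Constructs the onset times of a syllable train whose rate steps through
#' `rates` block by block — by default 4.3 to 4.7 syllables per second in
#' 0.1 syl/s increments, 60 syllables per block, the ramp used by the
#' spontaneous speech synchronization test. Within a block the inter-onset
#' interval is exactly `1/rate`.
#'
#' Two sizing modes are available, because a train can be specified either
#' by syllable count or by total duration:
#' * `mode = "syllables"` (default): each block contains
#'   `syllables_per_block` onsets; total duration is the sum of all
#'   inter-onset intervals.
#' * `mode = "duration"`: each block lasts `total_duration / length(rates)`
#'   seconds and is filled with as many onsets as fit at its rate.
#'
#' @param rates Numeric vector of block rates in syl/s (all `> 0`).
#' @param syllables_per_block Syllables per block (`mode = "syllables"`).
#' @param mode `"syllables"` or `"duration"`.
#' @param total_duration Total train duration in seconds
#'   (`mode = "duration"`).
#' @param fs If non-`NULL`, also render burst audio at this sampling rate:
#'   a 50 ms Hann-windowed noise burst at every onset.
#' @param seed Seed for the burst-noise carrier (only used when rendering
#'   audio).
#' @return A `stimulus_train` object with fields `onsets` (seconds, strictly
#'   increasing), `blocks` (block index per onset), `rates`, `duration`,
#'   `n_syllables` and optionally `audio`. `tidy()` returns one row per
#'   onset.
#' @export
#' @examples
#' tr <- make_stimulus_train()
#' tr$n_syllables # 300
#' round(tr$duration, 2) # 66.73
make_stimulus_train <- function(rates = seq(4.3, 4.7, by = 0.1),
                                syllables_per_block = 60,
                                mode = c("syllables", "duration"),
                                total_duration = NULL,
                                fs = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(rates) || length(rates) < 1L || any(rates <= 0) ||
      anyNA(rates)) {
    stop_invalid("`rates` must be positive syllable rates.")
  }
  if (mode == "syllables") {
    check_count(syllables_per_block, "syllables_per_block", lower = 1L)
    intervals <- rep(1 / rates, each = syllables_per_block)
    blocks <- rep(seq_along(rates), each = syllables_per_block)
    onsets <- c(0, cumsum(head(intervals, -1)))
    dur <- sum(intervals)
  } else {
    check_number(total_duration, "total_duration", lower = 1e-9)
    block_dur <- total_duration / length(rates)
    onsets <- numeric(0)
    blocks <- integer(0)
    for (b in seq_along(rates)) {
      t0 <- (b - 1) * block_dur
      ons <- seq(t0, t0 + block_dur - 1e-12, by = 1 / rates[b])
      onsets <- c(onsets, ons)
      blocks <- c(blocks, rep(b, length(ons)))
    }
    dur <- total_duration
  }
  out <- structure(
    list(onsets = onsets, blocks = blocks, rates = rates,
         duration = dur, n_syllables = length(onsets), audio = NULL),
    class = "stimulus_train"
  )
  if (!is.null(fs)) {
    out$audio <- with_seed(seed, render_bursts(onsets, dur, fs))
  }
  out
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf(
    "<stimulus_train: %d syllables, %d blocks (%.2f-%.2f syl/s), %.2f s%s>\n",
    x$n_syllables, length(x$rates), min(x$rates), max(x$rates), x$duration,
    if (is.null(x$audio)) "" else ", with audio"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stimulus_train <- function(x, ...) {
  tibble::tibble(onset = x$onsets, block = x$blocks,
                 rate = x$rates[x$blocks])
}

# Piecewise-linear syllable phase of a train: 2*pi per syllable, passing
# through 2*pi*(i-1) at the i-th onset, sampled at fs. Unwrapped.
stimulus_phase <- function(train, fs) {
  n <- round(train$duration * fs)
  t <- (seq_len(n) - 1) / fs
  anchors_t <- c(train$onsets, train$duration)
  anchors_p <- 2 * pi * (seq_along(anchors_t) - 1)
  approx(anchors_t, anchors_p, xout = t, rule = 2)$y
}

# Render Hann-windowed white-noise bursts (50 ms) at the given onset times
# over `dur` seconds of otherwise silent audio.
render_bursts <- function(onsets, dur, fs, burst_s = 0.05, amplitude = 0.5,
                          noise_floor = 0) {
  n <- round(dur * fs)
  x <- if (noise_floor > 0) rnorm(n, sd = noise_floor) else numeric(n)
  blen <- round(burst_s * fs)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = blen))
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    idx <- i0:min(i0 + blen - 1L, n)
    x[idx] <- x[idx] + amplitude * win[seq_along(idx)] * rnorm(length(idx))
  }
  audio_recording(pmax(pmin(x, 1), -1), fs)
}
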