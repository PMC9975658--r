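#' Generate burst-structured speech audio with known syllable nuclei
#'
#' Emulates spontaneous (whispered) speech for articulation-rate analysis:
#' short Hann-windowed noise bursts — unambiguous intensity peaks standing
#' in for syllable nuclei — placed inside voiced segments, with silent
#' pauses in between at a known noise floor. Because the nucleus times and
#' pause layout are known exactly, the ground-truth articulation rate
#' (bursts per second of voiced time) is available for every fixture.
#'
#' @param n_syllables Total number of bursts to place (`>= 0`). Bursts are
#'   distributed across voiced segments proportionally to segment duration
#'   and spaced evenly within each segment (optionally jittered).
#' @param voiced_segments A two-column matrix or list of `c(start, end)`
#'   pairs, in seconds, of voiced speech stretches.
#' @param pause_segments Like `voiced_segments`, for silent pauses. May be
#'   empty. Segments must not overlap.
#' @param noise_floor_db Background noise level in dB relative to burst
#'   amplitude (default -60).
#' @param jitter_frac Uniform jitter applied to each nucleus time, as a
#'   fraction of the local inter-burst spacing (default 0).
#' @param fs Audio sampling rate in Hz (default 8000).
#' @param burst_s Burst length in seconds (default 0.05).
#' @param seed Integer seed.
#' @return A `speech_bursts` object: `audio` (an [audio_recording()]),
#'   `nucleus_times`, `voiced_segments`, `pause_segments`,
#'   `voiced_duration`, and `true_rate` (`NA` when no voiced time or no
#'   bursts).
#' @export
#' @examples
#' sb <- make_speech_bursts(32, voiced_segments = rbind(c(0, 8)),
#'                          pause_segments = rbind(c(8, 10)), seed = 1)
#' sb$true_rate # 4 syl/s
make_speech_bursts <- function(n_syllables,
                               voiced_segments,
                               pause_segments = NULL,
                               noise_floor_db = -60,
                               jitter_frac = 0,
                               fs = 8000, burst_s = 0.05, seed = NULL) {
  check_count(n_syllables, "n_syllables")
  voiced <- as_segments(voiced_segments, "voiced_segments")
  pauses <- if (is.null(pause_segments) || length(pause_segments) == 0) {
    matrix(numeric(0), ncol = 2)
  } else {
    as_segments(pause_segments, "pause_segments")
  }
  all_seg <- rbind(voiced, pauses)
  ord <- order(all_seg[, 1])
  sorted <- all_seg[ord, , drop = FALSE]
  if (nrow(sorted) > 1 &&
      any(sorted[-1, 1] < sorted[-nrow(sorted), 2] - 1e-12)) {
    stop_invalid("Voiced and pause segments must not overlap.")
  }
  check_number(noise_floor_db, "noise_floor_db", upper = 0)
  check_number(jitter_frac, "jitter_frac", lower = 0, upper = 0.49)

  seg_dur <- voiced[, 2] - voiced[, 1]
  voiced_dur <- sum(seg_dur)
  # allot bursts to voiced segments proportionally (largest remainder)
  alloc <- if (n_syllables > 0) {
    raw <- n_syllables * seg_dur / voiced_dur
    base <- floor(raw)
    rem <- n_syllables - sum(base)
    extra <- head(order(raw - base, decreasing = TRUE), rem)
    base[extra] <- base[extra] + 1
    base
  } else {
    rep(0L, nrow(voiced))
  }
  with_seed(seed, {
    times <- unlist(lapply(seq_len(nrow(voiced)), function(i) {
      k <- alloc[i]
      if (k == 0) return(numeric(0))
      lo <- voiced[i, 1] + burst_s / 2
      hi <- voiced[i, 2] - burst_s / 2
      # bursts flush with the segment edges, so voiced stretches carry no
      # silent margins that would smear into adjacent pauses
      centres <- if (k == 1) mean(c(lo, hi)) else
        seq(lo, hi, length.out = k)
      if (jitter_frac > 0 && k > 1) {
        spacing <- (hi - lo) / (k - 1)
        centres <- pmin(pmax(centres + runif(k, -jitter_frac, jitter_frac) *
                               spacing, lo), hi)
      }
      centres
    }))
    total_dur <- max(all_seg[, 2])
    n <- round(total_dur * fs)
    floor_amp <- 10^(noise_floor_db / 20)
    x <- rnorm(n, sd = floor_amp)
    blen <- round(burst_s * fs)
    win <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = blen))
    for (tc in times) {
      i0 <- max(1L, round((tc - burst_s / 2) * fs) + 1L)
      idx <- i0:min(i0 + blen - 1L, n)
      x[idx] <- x[idx] + win[seq_along(idx)] * rnorm(length(idx), sd = 0.5)
    }
    structure(
      list(
        audio = audio_recording(pmax(pmin(x, 1), -1), fs),
        nucleus_times = sort(times),
        voiced_segments = voiced,
        pause_segments = pauses,
        voiced_duration = voiced_dur,
        true_rate = if (n_syllables > 0 && voiced_dur > 0) {
          n_syllables / voiced_dur
        } else {
          NA_real_
        }
      ),
      class = "speech_bursts"
    )
  })
}

as_segments <- function(x, name) {
  if (is.list(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) != 2L || any(x[, 2] <= x[, 1]) || any(x < 0) || anyNA(x)) {
    stop_invalid(sprintf(
      "`%s` must be (start, end) pairs with 0 <= start < end.", name))
  }
  x
}

#' @export
print.speech_bursts <- function(x, ...) {
  cat(sprintf(
    "<speech_bursts: %d nuclei, %.2f s voiced, true rate %s syl/s>\n",
    length(x$nucleus_times), x$voiced_duration,
    ifelse(is.na(x$true_rate), "NA", sprintf("%.2f", x$true_rate))))
  invisible(x)
}
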