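#' Detect syllable nuclei and estimate articulation rate
#'
#' Reimplements intensity-based syllable-nuclei counting: an intensity
#' contour (25 ms frames, 10 ms hop, dB scale) is scanned for local peaks
#' — candidate vowel centres — above an intensity threshold; a candidate is
#' accepted only when the contour dips at least `dip_db` below it before
#' the next peak, so amplitude ripples within one syllable are not counted
#' twice. Silent pauses (contiguous frames more than `silence_db` below the
#' contour maximum for at least `min_pause_s`) are excluded from the voiced
#' duration, and the articulation rate is nuclei per second of voiced time.
#'
#' @param audio An [audio_recording()] (mono, at least 0.5 s).
#' @param threshold_db Candidate peaks must exceed the median frame
#'   intensity by this many dB (default 2).
#' @param dip_db Minimum intensity dip between successive nuclei, dB
#'   (default 2).
#' @param silence_db Frames more than this many dB below the contour
#'   maximum count as silence (default 25).
#' @param min_pause_s Minimum silence run counted as a pause, seconds
#'   (default 0.3).
#' @param frame_s,hop_s Analysis frame length and hop, seconds.
#' @return A `nuclei_result` with `nucleus_times` (seconds), `n_nuclei`,
#'   `voiced_duration`, `articulation_rate` (`NA` when no nuclei or no
#'   voiced time), `pauses` (tibble) and the intensity `contour`.
#'   `glance()` returns the one-row summary.
#' @export
detect_syllable_nuclei <- function(audio, threshold_db = 2, dip_db = 2,
                                   silence_db = 25, min_pause_s = 0.3,
                                   frame_s = 0.025, hop_s = 0.01) {
  if (!inherits(audio, "audio_recording")) {
    stop_invalid_input("`audio` must be an audio_recording.")
  }
  if (duration(audio) < 0.5) {
    stop_invalid_input("Audio must be at least 0.5 s long.")
  }
  fs <- audio$sample_rate
  x <- audio$samples
  flen <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  starts <- seq.int(1L, length(x) - flen + 1L, by = hop)
  energy <- vapply(starts, function(s) mean(x[s:(s + flen - 1L)]^2),
                   numeric(1))
  db <- 10 * log10(energy + 1e-12)
  t_frame <- (starts - 1L + flen / 2) / fs
  contour <- tibble::tibble(time = t_frame, intensity_db = db)

  voicing_floor <- max(db) - silence_db
  # pauses: runs of sub-floor frames lasting at least min_pause_s
  silent <- db < voicing_floor
  runs <- rle(silent)
  ends <- cumsum(runs$lengths)
  starts_run <- ends - runs$lengths + 1L
  pause_idx <- which(runs$values & runs$lengths * hop_s >= min_pause_s)
  pauses <- tibble::tibble(
    start = t_frame[starts_run[pause_idx]] - frame_s / 2,
    end = t_frame[ends[pause_idx]] + frame_s / 2
  )
  pause_time <- sum(pmin(pauses$end, duration(audio)) -
                      pmax(pauses$start, 0))
  voiced_duration <- max(duration(audio) - pause_time, 0)

  # candidate peaks: local maxima above both the median-relative threshold
  # and the voicing floor
  thr <- max(median(db) + threshold_db, voicing_floor)
  n <- length(db)
  is_peak <- c(db[1] > db[2],
               db[2:(n - 1)] > db[1:(n - 2)] & db[2:(n - 1)] >= db[3:n],
               db[n] > db[n - 1]) & db > thr
  cand <- which(is_peak)
  accepted <- integer(0)
  for (i in cand) {
    if (length(accepted) == 0L) {
      accepted <- i
      next
    }
    last <- accepted[length(accepted)]
    dip <- min(db[last:i])
    if (db[i] - dip >= dip_db && db[last] - dip >= dip_db) {
      accepted <- c(accepted, i)
    } else if (db[i] > db[last]) {
      accepted[length(accepted)] <- i # ripple: keep the higher peak
    }
  }
  nucleus_times <- t_frame[accepted]
  n_nuclei <- length(nucleus_times)
  rate <- if (n_nuclei > 0 && voiced_duration > 0) {
    n_nuclei / voiced_duration
  } else {
    NA_real_
  }
  structure(
    list(nucleus_times = nucleus_times, n_nuclei = n_nuclei,
         voiced_duration = voiced_duration, articulation_rate = rate,
         pauses = pauses, contour = contour),
    class = "nuclei_result"
  )
}

#' @export
print.nuclei_result <- function(x, ...) {
  cat(sprintf(
    "<nuclei_result: %d nuclei / %.2f s voiced = %s syl/s (%d pauses)>\n",
    x$n_nuclei, x$voiced_duration,
    ifelse(is.na(x$articulation_rate), "NA",
           sprintf("%.2f", x$articulation_rate)),
    nrow(x$pauses)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nuclei_result <- function(x, ...) {
  tibble::tibble(nucleus = seq_along(x$nucleus_times),
                 time = x$nucleus_times)
}

#' @exportS3Method generics::glance
glance.nuclei_result <- function(x, ...) {
  tibble::tibble(n_nuclei = x$n_nuclei,
                 voiced_duration = x$voiced_duration,
                 n_pauses = nrow(x$pauses),
                 articulation_rate = x$articulation_rate)
}

#' @exportS3Method ggplot2::autoplot
autoplot.nuclei_result <- function(object, ...) {
  ggplot2::ggplot(object$contour,
                  ggplot2::aes(x = .data$time, y = .data$intensity_db)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$nucleus_times,
                        colour = "red", alpha = 0.5) +
    ggplot2::labs(x = "Time (s)", y = "Intensity (dB)",
                  title = sprintf("%d syllable nuclei", object$n_nuclei))
}

#' Per-participant mean articulation rate
#'
#' Averages trial-level articulation rates (unweighted) within participant,
#' as when each participant produces several fixed-length spontaneous
#' speech trials. Trials with undefined rates are dropped; participants
#' left without any valid trial are flagged.
#'
#' @param data A tibble with columns `participant` and `rate` (one row per
#'   trial; `rate` may contain `NA` for invalid trials).
#' @return A tibble with `participant`, `n_trials` (valid trials),
#'   `motor_rate` (mean rate; `NA` when no valid trial) and `missing`.
#' @export
#' @examples
#' articulation_rate_cohort(
#'   tibble::tibble(participant = c(1, 1, 2), rate = c(4.0, 4.4, 3.35)))
articulation_rate_cohort <- function(data) {
  if (!all(c("participant", "rate") %in% names(data))) {
    stop_invalid_input("`data` needs columns `participant` and `rate`.")
  }
  data |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_trials = sum(!is.na(.data$rate)),
      motor_rate = if (any(!is.na(.data$rate))) {
        mean(.data$rate, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(missing = .data$n_trials == 0L)
}
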