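#' Phase-locking value between two phase series
#'
#' The phase-locking value (PLV) of two instantaneous-phase series is
#' \deqn{\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T}
#'   e^{i(\theta_1(t) - \theta_2(t))}\right|,}
#' the resultant length of the phase differences: 1 for perfectly locked
#' signals, near 0 for unrelated ones.
#'
#' @param theta1,theta2 [phase_series()] objects or numeric phase vectors in
#'   radians, of equal length (and equal sampling rate when both are phase
#'   series).
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' plv(c(0, 1, 2), c(0.5, 1.5, 2.5)) # constant lag -> 1
plv <- function(theta1, theta2) {
  p1 <- phase_values(theta1)
  p2 <- phase_values(theta2)
  if (length(p1) != length(p2)) {
    stop_invalid_input(sprintf(
      "Phase series lengths differ (%d vs %d).", length(p1), length(p2)))
  }
  if (inherits(theta1, "phase_series") && inherits(theta2, "phase_series") &&
      theta1$sample_rate != theta2$sample_rate) {
    stop_invalid_input("Phase series have different sampling rates.")
  }
  if (length(p1) < 2L) {
    stop_invalid_input("PLV requires at least 2 time points.")
  }
  Mod(mean(exp(1i * (p1 - p2))))
}

phase_values <- function(x) {
  if (inherits(x, "phase_series")) return(x$phase)
  if (is.numeric(x)) return(as.numeric(x))
  stop_invalid_input("Expected a phase_series or numeric phase vector.")
}

#' Windowed PLV for one trial
#'
#' Computes the PLV in sliding windows (default 5 s long, overlapping by
#' 2 s, i.e. a 3 s hop), tiling the series from the start; a trailing
#' partial window is dropped. The trial-level PLV is the arithmetic mean of
#' the window PLVs.
#'
#' @inheritParams plv
#' @param sample_rate Sampling rate in Hz; taken from the phase series when
#'   available.
#' @param window_s Window length in seconds (default 5).
#' @param overlap_s Window overlap in seconds (default 2); the hop is
#'   `window_s - overlap_s`.
#' @return A `plv_result` object with elements `windows` (a tibble with one
#'   row per window: `window`, `start`, `end`, `plv`) and `trial_plv`.
#'   `tidy()` returns the window tibble; `glance()` the trial summary.
#' @export
windowed_plv <- function(theta1, theta2, sample_rate = NULL,
                         window_s = 5, overlap_s = 2) {
  p1 <- phase_values(theta1)
  p2 <- phase_values(theta2)
  if (length(p1) != length(p2)) {
    stop_invalid_input("Phase series lengths differ.")
  }
  if (is.null(sample_rate)) {
    if (!inherits(theta1, "phase_series")) {
      stop_invalid("Supply `sample_rate` when passing bare phase vectors.")
    }
    sample_rate <- theta1$sample_rate
  }
  check_number(window_s, "window_s", lower = 1e-9)
  check_number(overlap_s, "overlap_s", lower = 0)
  if (overlap_s >= window_s) {
    stop_invalid("`overlap_s` must be smaller than `window_s`.")
  }
  wlen <- round(window_s * sample_rate)
  hop <- round((window_s - overlap_s) * sample_rate)
  n <- length(p1)
  if (n < wlen) {
    stop_invalid_input(sprintf(
      "Series (%d samples) shorter than one %g s window.", n, window_s))
  }
  starts <- seq.int(1L, n - wlen + 1L, by = hop)
  plvs <- vapply(starts, function(s) {
    idx <- s:(s + wlen - 1L)
    Mod(mean(exp(1i * (p1[idx] - p2[idx]))))
  }, numeric(1))
  windows <- tibble::tibble(
    window = seq_along(starts),
    start = (starts - 1L) / sample_rate,
    end = (starts - 1L + wlen) / sample_rate,
    plv = plvs
  )
  structure(
    list(windows = windows, trial_plv = mean(plvs),
         window_s = window_s, overlap_s = overlap_s,
         sample_rate = sample_rate),
    class = "plv_result"
  )
}

#' @export
print.plv_result <- function(x, ...) {
  cat(sprintf("<plv_result: %d windows (%g s, overlap %g s), trial PLV %.3f>\n",
              nrow(x$windows), x$window_s, x$overlap_s, x$trial_plv))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.plv_result <- function(x, ...) x$windows

#' @exportS3Method generics::glance
glance.plv_result <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x$windows), trial_plv = x$trial_plv,
                 window_s = x$window_s, overlap_s = x$overlap_s)
}

#' @exportS3Method ggplot2::autoplot
autoplot.plv_result <- function(object, ...) {
  ggplot2::ggplot(object$windows,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$plv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$trial_plv, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Window centre (s)", y = "PLV",
                  title = sprintf("Trial PLV = %.3f", object$trial_plv))
}

#' Participant-level mean PLV
#'
#' Averages trial-level PLVs (unweighted) across the trials/runs of one
#' participant.
#'
#' @param trials A list of `plv_result` objects, or a numeric vector of
#'   trial PLVs.
#' @return A single mean PLV.
#' @export
participant_plv <- function(trials) {
  if (is.numeric(trials)) {
    vals <- as.numeric(trials)
  } else if (is.list(trials)) {
    vals <- vapply(trials, function(t) {
      if (inherits(t, "plv_result")) t$trial_plv
      else stop_invalid_input("List elements must be plv_result objects.")
    }, numeric(1))
  } else {
    stop_invalid_input("`trials` must be plv_results or trial PLVs.")
  }
  if (length(vals) == 0L) {
    stop_invalid_input("At least one trial is required.")
  }
  mean(vals)
}

#' Classify participants into high and low synchronizers
#'
#' Runs k-means with k = 2 (50 random restarts by default, keeping the
#' lowest within-cluster sum of squares) on the one-dimensional distribution
#' of participant mean PLVs and labels the cluster with the larger centre
#' `"HIGH"`, the other `"LOW"`. Because auditory-motor synchronization
#' strength is treated as bimodal, bimodality itself is assumed, not
#' re-tested; a silhouette-based separation diagnostic is reported so
#' degenerate cohorts are visible.
#'
#' @param data A data frame with columns `participant` and `plv`, or a bare
#'   numeric vector of participant PLVs.
#' @param seed Integer seed controlling the k-means restarts.
#' @param nstart Number of k-means restarts (default 50).
#' @return A `sync_classification` object; `tidy()` returns a tibble with
#'   `participant`, `plv`, `label`; `glance()` cluster centres, sizes,
#'   within-cluster SS and the mean silhouette width.
#' @export
#' @examples
#' cl <- classify_synchronizers(c(0.30, 0.35, 0.40, 0.70, 0.75, 0.80))
#' tidy(cl)
classify_synchronizers <- function(data, seed = 1L, nstart = 50L) {
  if (is.numeric(data)) {
    data <- tibble::tibble(participant = seq_along(data), plv = data)
  }
  if (!all(c("participant", "plv") %in% names(data))) {
    stop_invalid_input("`data` needs columns `participant` and `plv`.")
  }
  x <- data$plv
  if (length(x) < 2L) {
    stop_invalid_input("Need at least 2 participants to form 2 clusters.")
  }
  if (length(unique(x)) < 2L) {
    rlang::abort("All PLVs identical; 2-means clustering is degenerate.",
                 class = c("speechsync_degenerate_clustering",
                           "speechsync_error"))
  }
  if (length(x) == 2L) {
    # stats::kmeans requires k < n; with two participants the optimal
    # 2-means solution is one point per cluster
    km <- list(cluster = ifelse(x == max(x), 1L, 2L),
               centers = matrix(c(max(x), min(x))), tot.withinss = 0)
  } else {
    km <- with_seed(seed, kmeans(matrix(x, ncol = 1), centers = 2,
                                 nstart = nstart))
  }
  high_cluster <- which.max(km$centers)
  labels <- ifelse(km$cluster == high_cluster, "HIGH", "LOW")
  centers <- sort(as.numeric(km$centers))
  sil <- silhouette_1d(x, labels)
  structure(
    list(
      participants = tibble::tibble(
        participant = data$participant, plv = x,
        label = factor(labels, levels = c("LOW", "HIGH"))
      ),
      centers = c(LOW = centers[1], HIGH = centers[2]),
      tot_withinss = km$tot.withinss,
      silhouette = sil
    ),
    class = "sync_classification"
  )
}

# Mean silhouette width for a 1-D two-group labelling.
silhouette_1d <- function(x, labels) {
  s <- vapply(seq_along(x), function(i) {
    own <- x[labels == labels[i]]
    oth <- x[labels != labels[i]]
    a <- if (length(own) > 1) sum(abs(x[i] - own)) / (length(own) - 1) else 0
    b <- mean(abs(x[i] - oth))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' @export
print.sync_classification <- function(x, ...) {
  n <- table(x$participants$label)
  cat(sprintf(
    "<sync_classification: %d HIGH (centre %.3f), %d LOW (centre %.3f), mean silhouette %.2f>\n",
    n[["HIGH"]], x$centers[["HIGH"]], n[["LOW"]], x$centers[["LOW"]],
    x$silhouette))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sync_classification <- function(x, ...) x$participants

#' @exportS3Method generics::glance
glance.sync_classification <- function(x, ...) {
  n <- table(x$participants$label)
  tibble::tibble(
    center_low = x$centers[["LOW"]], center_high = x$centers[["HIGH"]],
    n_low = as.integer(n[["LOW"]]), n_high = as.integer(n[["HIGH"]]),
    tot_withinss = x$tot_withinss, silhouette = x$silhouette
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.sync_classification <- function(object, ...) {
  ggplot2::ggplot(object$participants,
                  ggplot2::aes(x = .data$plv, fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = 0.025, boundary = 0, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$centers, linetype = 2) +
    ggplot2::labs(x = "Participant mean PLV", y = "Participants",
                  fill = NULL)
}
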