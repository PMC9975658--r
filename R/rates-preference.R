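#' Exclude participants who failed catch trials
#'
#' Engagement screening for the 2IFC preference task: participants whose
#' catch-trial accuracy falls strictly below the threshold (default 75%
#' correct) are removed; performance exactly at the threshold is retained.
#'
#' @param data Either a 2IFC trial tibble containing `participant`,
#'   `is_catch` and `catch_correct` (accuracy is then computed per
#'   participant), or a participant summary with columns `participant` and
#'   `catch_accuracy` in percent.
#' @param threshold Exclusion threshold in percent (default 75).
#' @return `data` restricted to retained participants, with the excluded
#'   participant summary in attribute `"excluded"`. Participants with no
#'   catch trials are retained (accuracy `NA`).
#' @export
#' @examples
#' d <- tibble::tibble(participant = 1:3,
#'                     catch_accuracy = c(74.9, 75, 98.48))
#' exclude_catch_failures(d)$participant
exclude_catch_failures <- function(data, threshold = 75) {
  check_number(threshold, "threshold", lower = 0, upper = 100)
  if ("catch_accuracy" %in% names(data)) {
    acc <- dplyr::distinct(data, .data$participant, .data$catch_accuracy)
  } else if (all(c("is_catch", "catch_correct") %in% names(data))) {
    acc <- data |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(
        catch_accuracy = if (any(.data$is_catch)) {
          100 * mean(.data$catch_correct[.data$is_catch])
        } else {
          NA_real_
        },
        .groups = "drop"
      )
  } else {
    stop_invalid_input(
      "`data` needs `catch_accuracy` or `is_catch`/`catch_correct` columns.")
  }
  if (any(acc$catch_accuracy < 0 | acc$catch_accuracy > 100, na.rm = TRUE)) {
    stop_invalid_input("Catch accuracies must lie in [0, 100].")
  }
  drop <- acc$participant[!is.na(acc$catch_accuracy) &
                            acc$catch_accuracy < threshold]
  out <- dplyr::filter(data, !.data$participant %in% drop)
  attr(out, "excluded") <- dplyr::filter(acc, .data$participant %in% drop)
  out
}

#' Aggregate 2IFC trials into a preferred-frequency distribution
#'
#' Counts, over all non-catch trials, how often each grid rate was the
#' preferred item. Self-pairs contribute one count to their rate like any
#' other trial. The counts conserve trials: their sum equals the number of
#' non-catch trials used.
#'
#' @param trials A 2IFC trial tibble with columns `rate_a`, `rate_b`,
#'   `choice` (and optionally `is_catch`), as produced by
#'   [make_2ifc_trials()].
#' @param rate_grid Optional explicit grid; defaults to all rates appearing
#'   in the trials.
#' @return A `preference_distribution`: tibble `distribution` with `rate`
#'   and `count`, plus `n_trials_used`.
#' @export
build_preference_distribution <- function(trials, rate_grid = NULL) {
  needed <- c("rate_a", "rate_b", "choice")
  if (!all(needed %in% names(trials))) {
    stop_invalid_input("`trials` needs columns rate_a, rate_b, choice.")
  }
  if ("is_catch" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$is_catch)
  }
  bad <- which(trials$choice != trials$rate_a &
                 trials$choice != trials$rate_b)
  if (length(bad) > 0) {
    stop_invalid_input(sprintf(
      "Choice not among the trial's two rates in %d trial(s), e.g. row %d.",
      length(bad), bad[1]))
  }
  grid <- sort(rate_grid %||% unique(c(trials$rate_a, trials$rate_b)))
  counts <- vapply(grid, function(r) sum(trials$choice == r), numeric(1))
  structure(
    list(
      distribution = tibble::tibble(rate = grid, count = as.integer(counts)),
      n_trials_used = nrow(trials)
    ),
    class = "preference_distribution"
  )
}

#' @export
print.preference_distribution <- function(x, ...) {
  cat(sprintf("<preference_distribution: %d trials over %d rates>\n",
              x$n_trials_used, nrow(x$distribution)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.preference_distribution <- function(x, ...) x$distribution

#' Fit a Gaussian to a preferred-frequency distribution
#'
#' Least-squares fit of \eqn{a \exp(-(r-\mu)^2/(2\sigma^2)) + d} to the
#' preferred-item counts over the rate grid. The peak \eqn{\mu} indexes the
#' preferred auditory rate, and the full width at half maximum,
#' \eqn{\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma}, indexes the specificity of
#' the preference (smaller = sharper). The additive baseline `d` absorbs
#' the irreducible count floor of forced-choice data — every rate wins some
#' trials (self-pairs guarantee it) — which would otherwise bias the width
#' upward; set `baseline = FALSE` for the pure Gaussian.
#'
#' @param dist A [build_preference_distribution()] result (or a tibble with
#'   `rate` and `count`).
#' @param baseline Fit an additive offset (default `TRUE`).
#' @return A `gaussian_fit` with `peak`, `sigma`, `fwhm`
#'   (`= 2 * sqrt(2 * log(2)) * sigma`), `amplitude`, `baseline`,
#'   `fit_rmse`. `tidy()` gives the parameter table, `glance()` the one-row
#'   summary, `autoplot()` the counts with the fitted curve.
#' @export
fit_gaussian_preference <- function(dist, baseline = TRUE) {
  d <- if (inherits(dist, "preference_distribution")) {
    dist$distribution
  } else {
    dist
  }
  if (!all(c("rate", "count") %in% names(d))) {
    stop_invalid_input("`dist` needs columns `rate` and `count`.")
  }
  if (sum(d$count > 0) < 3L) {
    stop_invalid_input(
      "At least 3 rates with nonzero counts are needed for a Gaussian fit.")
  }
  r <- d$rate
  y <- as.numeric(d$count)
  span <- diff(range(r))
  mode_r <- r[which.max(y)]
  sigma0 <- max(sqrt(sum(y * (r - sum(r * y) / sum(y))^2) / sum(y)),
                span / 20)
  start <- list(a = max(y) - min(y), mu = mode_r, sigma = sigma0,
                d = min(y))
  lower <- c(a = 1e-9, mu = min(r) - 1, sigma = span / 100, d = 0)
  upper <- c(a = 2 * max(y), mu = max(r) + 1, sigma = 2 * span,
             d = max(y))
  if (!baseline) {
    start$d <- NULL
    lower <- lower[names(lower) != "d"]
    upper <- upper[names(upper) != "d"]
  }
  form <- if (baseline) {
    count ~ a * exp(-(rate - mu)^2 / (2 * sigma^2)) + d
  } else {
    count ~ a * exp(-(rate - mu)^2 / (2 * sigma^2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = tibble::tibble(rate = r, count = y),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      rlang::abort(
        paste0("Gaussian preference fit failed to converge: ",
               conditionMessage(e)),
        class = c("speechsync_fit_failure", "speechsync_error"))
    }
  )
  cf <- coef(fit)
  resid <- y - predict(fit)
  structure(
    list(
      peak = unname(cf["mu"]),
      sigma = unname(cf["sigma"]),
      fwhm = 2 * sqrt(2 * log(2)) * unname(cf["sigma"]),
      amplitude = unname(cf["a"]),
      baseline = if (baseline) unname(cf["d"]) else 0,
      fit_rmse = sqrt(mean(resid^2)),
      data = tibble::tibble(rate = r, count = y, fitted = predict(fit))
    ),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit: peak %.2f syl/s, FWHM %.2f syl/s (rmse %.2f)>\n",
              x$peak, x$fwhm, x$fit_rmse))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("peak", "sigma", "fwhm", "amplitude", "baseline"),
    estimate = c(x$peak, x$sigma, x$fwhm, x$amplitude, x$baseline)
  )
}

#' @exportS3Method generics::glance
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(peak = x$peak, sigma = x$sigma, fwhm = x$fwhm,
                 amplitude = x$amplitude, baseline = x$baseline,
                 fit_rmse = x$fit_rmse)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gaussian_fit <- function(object, ...) {
  grid <- tibble::tibble(
    rate = seq(min(object$data$rate), max(object$data$rate),
               length.out = 200))
  grid$fitted <- object$amplitude *
    exp(-(grid$rate - object$peak)^2 / (2 * object$sigma^2)) +
    object$baseline
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "red") +
    ggplot2::geom_vline(xintercept = object$peak, linetype = 2) +
    ggplot2::labs(x = "Syllabic rate (syl/s)", y = "Times preferred",
                  title = sprintf("Peak %.2f syl/s, FWHM %.2f syl/s",
                                  object$peak, object$fwhm))
}
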