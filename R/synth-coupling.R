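#' Expected PLV of von Mises phase noise
#'
#' If the phase difference between two signals is von Mises distributed
#' with concentration `kappa`, the expected resultant length — and hence
#' the expected PLV for long series — is the Bessel ratio
#' \eqn{I_1(\kappa)/I_0(\kappa)}. `plv_to_kappa()` inverts the relation
#' numerically.
#'
#' @param kappa Concentration parameter, `>= 0` (`Inf` allowed: no noise).
#' @return Expected PLV in `[0, 1]`.
#' @export
#' @examples
#' vm_expected_plv(2) # about 0.698
vm_expected_plv <- function(kappa) {
  check_number(kappa, "kappa", lower = 0, allow_inf = TRUE)
  if (is.infinite(kappa)) return(1)
  if (kappa == 0) return(0)
  # scaled Bessel functions avoid overflow at large kappa
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' @rdname vm_expected_plv
#' @param target_plv Expected PLV in `[0, 1)` to invert.
#' @export
plv_to_kappa <- function(target_plv) {
  check_number(target_plv, "target_plv", lower = 0, upper = 1)
  if (target_plv == 0) return(0)
  if (target_plv >= 1) return(Inf)
  uniroot(function(k) vm_expected_plv(k) - target_plv,
          lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}

# Quantile function of the zero-mean von Mises distribution, as a
# vectorized closure. Built from a fine grid of the CDF; for very large
# kappa the wrapped-normal limit N(0, 1/kappa) is used.
vm_quantile_fun <- function(kappa, grid_n = 8192) {
  if (is.infinite(kappa)) return(function(u) rep(0, length(u)))
  if (kappa > 50) {
    s <- 1 / sqrt(kappa)
    return(function(u) qnorm(u, sd = s))
  }
  x <- seq(-pi, pi, length.out = grid_n)
  dens <- exp(kappa * (cos(x) - 1))
  cdf <- cumsum(dens) - dens / 2
  cdf <- cdf / (sum(dens) - (dens[1] + dens[grid_n]) / 2)
  cdf <- pmin(pmax(cdf, 0), 1)
  function(u) approx(cdf, x, xout = u, rule = 2, ties = "ordered")$y
}

# Smooth stationary phase-noise process with an exactly von Mises marginal:
# a unit-variance AR(1) (correlation time tau_s) mapped through the von
# Mises quantile function (Gaussian copula). This keeps the concentration ->
# expected-PLV identity intact while the noise stays slow and band-limited,
# unlike low-pass filtering i.i.d. circular noise, which would shrink its
# dispersion.
vm_noise_process <- function(n, fs, kappa, tau_s = 0.1) {
  if (is.infinite(kappa)) return(numeric(n))
  rho <- exp(-1 / (fs * tau_s))
  z <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - rho^2)), rho,
                                method = "recursive", init = rnorm(1)))
  vm_quantile_fun(kappa)(pnorm(z))
}

#' Generate a coupled stimulus/production phase pair
#'
#' Builds the narrowband phase of a syllable-train stimulus and a simulated
#' produced-speech phase that follows it with a fixed mean lag plus slowly
#' varying von Mises phase noise of concentration `kappa`. The noise has an
#' exactly von Mises marginal at every sample (see details in the package
#' vignette), so the expected PLV of the pair equals
#' [vm_expected_plv()]`(kappa)` up to finite-length fluctuation.
#'
#' @param train A [make_stimulus_train()] result, or `NULL` to use a
#'   constant 4.5 syl/s rhythm of length `duration`.
#' @param kappa von Mises concentration of the production phase noise
#'   (`>= 0`, `Inf` = perfectly locked).
#' @param mean_lag Mean production lag in radians.
#' @param fs Sampling rate of the phase series in Hz (default 100).
#' @param duration Duration in seconds when `train` is `NULL` (default 80).
#' @param tau_s Correlation time of the phase noise in seconds
#'   (default 0.1).
#' @param seed Optional integer seed.
#' @return A list with [phase_series()] elements `theta1` (stimulus) and
#'   `theta2` (production), plus `kappa` and `expected_plv`.
#' @export
make_coupled_phases <- function(train = NULL, kappa = 2, mean_lag = 0,
                                fs = 100, duration = 80, tau_s = 0.1,
                                seed = NULL) {
  check_number(kappa, "kappa", lower = 0, allow_inf = TRUE)
  check_number(mean_lag, "mean_lag")
  check_number(fs, "fs", lower = 1e-9)
  if (is.null(train)) {
    check_number(duration, "duration", lower = 1e-9)
    n <- round(duration * fs)
    theta1 <- 2 * pi * 4.5 * (seq_len(n) - 1) / fs
    max_rate <- 4.5
  } else {
    if (!inherits(train, "stimulus_train")) {
      stop_invalid_input("`train` must be a stimulus_train.")
    }
    n <- round(train$duration * fs)
    theta1 <- stimulus_phase(train, fs)
    max_rate <- max(train$rates)
  }
  if (fs <= 2 * max_rate) {
    stop_invalid(sprintf(
      "`fs` (%g Hz) must exceed twice the maximum syllable rate (%g).",
      fs, max_rate))
  }
  eps <- with_seed(seed, vm_noise_process(n, fs, kappa, tau_s))
  list(
    theta1 = phase_series(theta1, fs, band = c(3.5, 5.5)),
    theta2 = phase_series(theta1 + mean_lag + eps, fs, band = c(3.5, 5.5)),
    kappa = kappa,
    expected_plv = vm_expected_plv(kappa)
  )
}

#' Simulate a cohort of high and low synchronizers
#'
#' `make_population()` generates, for each participant, coupled
#' stimulus/production phase pairs whose phase-noise concentration is drawn
#' so that the cohort's participant-level windowed PLVs form the familiar
#' bimodal distribution (defaults aim at group means near 0.73 and 0.36
#' with spread near 0.09, the empirically observed regime). The true group
#' label is returned with every participant.
#'
#' `make_plv_cohort()` skips the signal level and draws participant mean
#' PLVs directly from two truncated Gaussians; it is the light-weight input
#' for classifier studies.
#'
#' @param n_high,n_low Number of high/low synchronizers.
#' @param kappa_high,kappa_low Median phase-noise concentration per group;
#'   defaults are tuned so that realized windowed group mean PLVs land near
#'   0.73 / 0.36.
#' @param plv_sd Between-participant spread of the targeted expected PLV
#'   (default 0.09).
#' @param trial_count Trials (runs) per participant (default 2).
#' @param trial_duration Trial length in seconds (default 80).
#' @param fs Phase sampling rate in Hz (default 100).
#' @param seed Integer seed.
#' @return A tibble with one row per participant: `participant`, `label`
#'   (`"HIGH"`/`"LOW"` ground truth), `kappa`, and a `trials` list-column of
#'   [make_coupled_phases()] results.
#' @export
make_population <- function(n_high = 41, n_low = 41,
                            kappa_high = 2.15, kappa_low = 0.72,
                            plv_sd = 0.09,
                            trial_count = 2, trial_duration = 80,
                            fs = 100, seed = NULL) {
  check_count(n_high, "n_high"); check_count(n_low, "n_low")
  if (n_high + n_low < 1L) {
    stop_invalid("At least one participant is required.")
  }
  if (n_high > 0 && n_low > 0 && kappa_high <= kappa_low) {
    stop_invalid("`kappa_high` must exceed `kappa_low`.")
  }
  check_count(trial_count, "trial_count", lower = 1L)
  with_seed(seed, {
    labels <- rep(c("HIGH", "LOW"), c(n_high, n_low))
    base_plv <- ifelse(labels == "HIGH",
                       vm_expected_plv(kappa_high),
                       vm_expected_plv(kappa_low))
    target <- pmin(pmax(rnorm(length(labels), base_plv, plv_sd), 0.03), 0.97)
    kappas <- vapply(target, plv_to_kappa, numeric(1))
    trials <- lapply(kappas, function(k) {
      lapply(seq_len(trial_count), function(i) {
        make_coupled_phases(train = NULL, kappa = k,
                            mean_lag = runif(1, -pi, pi),
                            fs = fs, duration = trial_duration)
      })
    })
    tibble::tibble(
      participant = seq_along(labels),
      label = factor(labels, levels = c("LOW", "HIGH")),
      kappa = kappas,
      trials = trials
    )
  })
}

#' @rdname make_population
#' @param mean_high,mean_low Group mean PLVs (defaults 0.73 / 0.36).
#' @export
make_plv_cohort <- function(n_high = 41, n_low = 41,
                            mean_high = 0.73, mean_low = 0.36,
                            plv_sd = 0.09, seed = NULL) {
  check_count(n_high, "n_high"); check_count(n_low, "n_low")
  with_seed(seed, {
    labels <- rep(c("HIGH", "LOW"), c(n_high, n_low))
    mu <- ifelse(labels == "HIGH", mean_high, mean_low)
    plvs <- pmin(pmax(rnorm(length(labels), mu, plv_sd), 0.01), 0.99)
    tibble::tibble(
      participant = seq_along(labels),
      label = factor(labels, levels = c("LOW", "HIGH")),
      plv = plvs
    )
  })
}
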