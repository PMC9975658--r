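test_that("stimulus train follows the block-rate schedule exactly", {
  tr <- make_stimulus_train()
  expect_equal(tr$n_syllables, 300)
  expect_equal(tr$duration, sum(60 / seq(4.3, 4.7, by = 0.1)),
               tolerance = 1e-12)
  expect_true(all(diff(tr$onsets) > 0))
  # within each block the inter-onset interval is 1/rate
  d <- tidy(tr)
  for (b in unique(d$block)) {
    ons <- d$onset[d$block == b]
    if (length(ons) > 1) {
      expect_equal(diff(ons), rep(1 / d$rate[d$block == b][1],
                                  length(ons) - 1),
                   tolerance = 1e-9)
    }
  }
  single <- make_stimulus_train(rates = 4, syllables_per_block = 4)
  expect_equal(single$onsets, c(0, 0.25, 0.5, 0.75))
  expect_error(make_stimulus_train(rates = c(4, -1)),
               class = "speechsync_invalid_parameter")
})

test_that("duration mode fills blocks of equal length", {
  tr <- make_stimulus_train(mode = "duration", total_duration = 80)
  expect_equal(tr$duration, 80)
  expect_equal(length(unique(tr$blocks)), 5)
  # onsets of block b start at its block boundary
  expect_equal(min(tr$onsets[tr$blocks == 3]), 2 * 16)
  expect_true(all(diff(tr$onsets) > 0))
})

test_that("coupled phases honour the concentration parameter", {
  locked <- make_coupled_phases(kappa = Inf, duration = 20)
  expect_equal(plv(locked$theta1, locked$theta2), 1, tolerance = 1e-12)
  lagged <- make_coupled_phases(kappa = Inf, mean_lag = 1.2, duration = 20)
  expect_equal(plv(lagged$theta1, lagged$theta2), 1, tolerance = 1e-12)
  # kappa = 0: uniform phase noise, PLV collapses to O(1/sqrt(T))
  free <- make_coupled_phases(kappa = 0, duration = 80, seed = 11)
  expect_lt(plv(free$theta1, free$theta2), 0.25)
  expect_error(make_coupled_phases(kappa = -1),
               class = "speechsync_invalid_parameter")
  # determinism under seed
  a <- make_coupled_phases(kappa = 2, duration = 10, seed = 7)
  b <- make_coupled_phases(kappa = 2, duration = 10, seed = 7)
  expect_identical(a$theta2$phase, b$theta2$phase)
})

test_that("von Mises coupling matches the Bessel-ratio expectation", {
  # Monte-Carlo check of E[PLV] = I1(kappa)/I0(kappa) at moderate n
  for (kappa in c(1, 4)) {
    plvs <- vapply(1:40, function(i) {
      cp <- make_coupled_phases(kappa = kappa, duration = 80,
                                seed = 1000 + i)
      plv(cp$theta1, cp$theta2)
    }, numeric(1))
    expect_lt(abs(mean(plvs) - vm_expected_plv(kappa)), 0.02)
  }
})

test_that("population generator labels and reproducibility", {
  pop0 <- make_population(n_high = 0, n_low = 5, trial_count = 1,
                          trial_duration = 6, seed = 2)
  expect_true(all(pop0$label == "LOW"))
  p1 <- make_population(n_high = 2, n_low = 2, trial_count = 1,
                        trial_duration = 6, seed = 9)
  p2 <- make_population(n_high = 2, n_low = 2, trial_count = 1,
                        trial_duration = 6, seed = 9)
  expect_identical(p1$kappa, p2$kappa)
  expect_identical(p1$trials[[1]][[1]]$theta2$phase,
                   p2$trials[[1]][[1]]$theta2$phase)
  expect_error(make_population(kappa_high = 0.5, kappa_low = 0.7),
               class = "speechsync_invalid_parameter")
})

test_that("speech bursts have known rate and respect segment layout", {
  sb <- make_speech_bursts(32, voiced_segments = rbind(c(0, 8)),
                           pause_segments = rbind(c(8, 10)), seed = 1)
  expect_equal(sb$true_rate, 4.0)
  expect_equal(length(sb$nucleus_times), 32)
  expect_true(all(sb$nucleus_times >= 0 & sb$nucleus_times <= 8))
  expect_equal(duration(sb$audio), 10)

  empty <- make_speech_bursts(0, voiced_segments = rbind(c(0, 5)))
  expect_true(is.na(empty$true_rate))

  sb2 <- make_speech_bursts(20, voiced_segments = rbind(c(0, 5)), seed = 2)
  expect_equal(sb2$true_rate, 4.0)

  expect_error(
    make_speech_bursts(5, voiced_segments = rbind(c(0, 4)),
                       pause_segments = rbind(c(3, 5))),
    class = "speechsync_invalid_parameter")
})

test_that("2IFC choices follow the latent Gaussian preference", {
  # noise-free: the rate nearer the peak always wins
  tr <- make_2ifc_trials(true_peak = 5.75, true_fwhm = 2,
                         rate_grid = c(3.00, 5.75), trials_per_pair = 10,
                         decision_noise = 0, seed = 3)
  hard <- dplyr::filter(tr, rate_a != rate_b)
  expect_true(all(hard$choice == 5.75))
  # self pairs resolve by fair coin
  self <- dplyr::filter(tr, rate_a == rate_b, rate_a == 3.00)
  expect_true(all(self$choice == 3.00))
  big <- make_2ifc_trials(true_peak = 5.75, true_fwhm = 2,
                          rate_grid = c(3.00, 5.75),
                          trials_per_pair = 400, decision_noise = 0,
                          seed = 4)
  picks <- dplyr::filter(big, rate_a == 3.00, rate_b == 3.00)
  # both intervals carry the same rate; the count split is the coin's
  expect_equal(nrow(picks), 400)
  expect_error(make_2ifc_trials(true_fwhm = 0),
               class = "speechsync_invalid_parameter")
  expect_error(make_2ifc_trials(true_peak = 99),
               class = "speechsync_invalid_parameter")
})

test_that("comprehension generator matches its own probabilities", {
  flat <- make_comprehension_trials(
    n_participants = 40, n_items = 60,
    coefficients = c("(Intercept)" = 0, syllabic_rate = 0),
    sd_participant = 0, sd_item = 0, sd_rate_slope = 0, seed = 5)
  expect_lt(abs(mean(flat$trials$outcome) - 0.5),
            4 * sqrt(0.25 / nrow(flat$trials)))
  sim <- make_comprehension_trials(n_participants = 30, n_items = 40,
                                   seed = 6)
  # empirical accuracy within binomial error of the generating mean
  n <- nrow(sim$trials)
  p_bar <- mean(sim$trials$p_true)
  expect_lt(abs(mean(sim$trials$outcome) - p_bar),
            4 * sqrt(p_bar * (1 - p_bar) / n))
  expect_error(
    make_comprehension_trials(coefficients = c("(Intercept)" = NaN)),
    class = "speechsync_invalid_parameter")
})
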