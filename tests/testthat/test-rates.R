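test_that("nuclei detection recovers known burst counts and rates", {
  sb <- make_speech_bursts(32, voiced_segments = rbind(c(0, 8)),
                           pause_segments = rbind(c(8, 10)), seed = 1)
  res <- detect_syllable_nuclei(sb$audio)
  expect_equal(res$n_nuclei, 32)
  expect_equal(res$articulation_rate, 4.0, tolerance = 0.05)

  sb2 <- make_speech_bursts(20, voiced_segments = rbind(c(0, 5)),
                            seed = 2)
  res2 <- detect_syllable_nuclei(sb2$audio)
  expect_equal(res2$n_nuclei, 20)
  expect_equal(res2$articulation_rate, 4.0, tolerance = 0.05)

  silence <- audio_recording(rnorm(8000, sd = 1e-4), 8000)
  res0 <- detect_syllable_nuclei(silence)
  expect_equal(res0$n_nuclei, 0)
  expect_true(is.na(res0$articulation_rate))
})

test_that("detected nucleus times track jittered ground truth", {
  sb <- make_speech_bursts(24, voiced_segments = rbind(c(0, 6)),
                           jitter_frac = 0.15, seed = 3)
  res <- detect_syllable_nuclei(sb$audio)
  expect_equal(res$n_nuclei, 24)
  err <- abs(res$nucleus_times - sb$nucleus_times)
  expect_lt(max(err), 0.02)
})

test_that("articulation rate ignores inserted pauses", {
  a <- make_speech_bursts(32, voiced_segments = rbind(c(0, 8)), seed = 4)
  b <- make_speech_bursts(32, voiced_segments = rbind(c(0, 8)),
                          pause_segments = rbind(c(8, 10)), seed = 4)
  ra <- detect_syllable_nuclei(a$audio)$articulation_rate
  rb <- detect_syllable_nuclei(b$audio)$articulation_rate
  expect_lt(abs(ra - rb) / ra, 0.01)
})

test_that("cohort articulation rates average per participant", {
  out <- articulation_rate_cohort(tibble::tibble(
    participant = c(1, 1, 2, 3),
    rate = c(4.0, 4.4, 3.35, NA)))
  expect_equal(out$motor_rate[out$participant == 1], 4.2)
  expect_equal(out$motor_rate[out$participant == 2], 3.35)
  expect_true(out$missing[out$participant == 3])
})

test_that("catch-trial screening keeps the boundary case", {
  d <- tibble::tibble(participant = 1:3,
                      catch_accuracy = c(74.9, 75.0, 98.48))
  kept <- exclude_catch_failures(d)
  expect_equal(kept$participant, c(2, 3))
  expect_equal(attr(kept, "excluded")$participant, 1)
  # computed from raw catch trials too
  tr <- dplyr::bind_rows(
    make_2ifc_trials(trials_per_pair = 1, n_catch = 20,
                     catch_accuracy = 1, participant = 1, seed = 1),
    make_2ifc_trials(trials_per_pair = 1, n_catch = 20,
                     catch_accuracy = 0, participant = 2, seed = 2))
  kept2 <- exclude_catch_failures(tr)
  expect_equal(unique(kept2$participant), 1)
})

test_that("preference distribution conserves non-catch trials", {
  tr <- make_2ifc_trials(trials_per_pair = 5, n_catch = 12, seed = 5)
  dist <- build_preference_distribution(tr)
  expect_equal(sum(dist$distribution$count), 7 * 7 * 5)
  expect_equal(dist$n_trials_used, 7 * 7 * 5)

  simple <- tibble::tibble(rate_a = rep(3, 3), rate_b = rep(5.75, 3),
                           choice = rep(5.75, 3))
  d2 <- build_preference_distribution(simple)
  expect_equal(d2$distribution$count[d2$distribution$rate == 5.75], 3L)

  bad <- tibble::tibble(rate_a = 3, rate_b = 5.75, choice = 4)
  expect_error(build_preference_distribution(bad),
               class = "speechsync_invalid_input")
})

test_that("noise-free preferences concentrate at the nearest grid rate", {
  tr <- make_2ifc_trials(true_peak = 5.6, true_fwhm = 2,
                         trials_per_pair = 10, decision_noise = 0,
                         seed = 6)
  dist <- build_preference_distribution(tr)
  d <- dist$distribution
  expect_equal(d$rate[which.max(d$count)], 5.75)
})

test_that("gaussian fit honours the FWHM identity and symmetry", {
  grid <- seq(2, 10, by = 1)
  counts <- round(100 * exp(-(grid - 5.75)^2 / 2)) # sigma = 1
  fit <- fit_gaussian_preference(tibble::tibble(rate = grid,
                                                count = counts))
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * fit$sigma,
               tolerance = 1e-12)
  expect_equal(fit$fwhm, 2.3548, tolerance = 0.02)
  expect_equal(fit$peak, 5.75, tolerance = 0.01)

  # scale invariance of peak and FWHM
  fit10 <- fit_gaussian_preference(tibble::tibble(rate = grid,
                                                  count = counts * 10))
  expect_equal(fit10$peak, fit$peak, tolerance = 1e-6)
  expect_equal(fit10$fwhm, fit$fwhm, tolerance = 1e-6)

  expect_error(
    fit_gaussian_preference(tibble::tibble(rate = grid,
                                           count = c(5, 3, rep(0, 7)))),
    class = "speechsync_invalid_input")
})

test_that("preference peak and width are recoverable from 2IFC data", {
  est <- vapply(1:40, function(i) {
    tr <- make_2ifc_trials(true_peak = 5.6, true_fwhm = 2, seed = 700 + i)
    fit <- fit_gaussian_preference(build_preference_distribution(tr))
    c(fit$peak, fit$fwhm)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 5.6), 0.1)
  expect_lt(abs(mean(est[2, ]) - 2.0) / 2.0, 0.1)
})
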