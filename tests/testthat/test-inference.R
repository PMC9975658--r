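test_that("predictor table z-scores and joins correctly", {
  trials <- tibble::tibble(participant = rep(1:4, each = 3),
                           item = rep(1:3, 4),
                           outcome = rbinom(12, 1, 0.5))
  pd <- tibble::tibble(participant = 1:4, motor_rate = c(3.9, 4.2, 4.6, 5))
  id <- tibble::tibble(item = 1:3, syllabic_rate = c(5, 10, 15))
  tab <- build_predictor_table(trials, pd, id,
                               z = c("motor_rate", "syllabic_rate"))
  expect_equal(mean(tab$motor_rate), 0, tolerance = 1e-12)
  expect_equal(sd(tab$motor_rate), 1, tolerance = 1e-12)
  expect_equal(sd(tab$syllabic_rate), 1, tolerance = 1e-12)

  expect_error(build_predictor_table(trials, pd[1:2, ], id),
               class = "speechsync_invalid_input")
  expect_error(
    build_predictor_table(trials, dplyr::bind_rows(pd, pd[1, ]), id),
    class = "speechsync_invalid_input")
})

test_that("VIF flags collinearity and passes orthogonal designs", {
  set.seed(20)
  n <- 400
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  v <- vif(cbind(a = x1, b = x2))
  expect_true(all(v < 1.05))
  # an exact duplicate is perfectly collinear
  v2 <- vif(cbind(a = x1, b = x1))
  expect_true(!is.finite(v2[["b"]]) || v2[["b"]] > 1e6)
  trials <- tibble::tibble(participant = 1:n, item = 1:n,
                           outcome = rbinom(n, 1, 0.5),
                           p1 = x1, p2 = x1 + 1e-14 * x2)
  expect_error(build_predictor_table(trials, z = c("p1", "p2"),
                                     vif_bound = 10),
               class = "speechsync_invalid_input")
})

test_that("GLMM reporting identities hold on a small fit", {
  sim <- make_comprehension_trials(n_participants = 20, n_items = 40,
                                   seed = 21)
  fit <- fit_binomial_glmm(sim$trials,
                           fixed = c("syllabic_rate", "motor_rate"),
                           nAGQ = 0)
  co <- tidy(fit)
  expect_equal(co$odds_ratio, exp(co$estimate), tolerance = 1e-12)
  expect_equal(fit$aic, 2 * fit$df - 2 * fit$log_likelihood,
               tolerance = 1e-8)
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))
  expect_error(fit_binomial_glmm(sim$trials, fixed = "no_such_column"),
               class = "speechsync_invalid_input")
})

test_that("fixed effects are recovered without random variation", {
  sim <- make_comprehension_trials(
    n_participants = 60, n_items = 150,
    coefficients = c("(Intercept)" = 1.0, syllabic_rate = log(0.65),
                     motor_rate = log(1.2)),
    sd_participant = 0, sd_item = 0, sd_rate_slope = 0, seed = 22)
  fit <- fit_binomial_glmm(sim$trials,
                           fixed = c("syllabic_rate", "motor_rate"),
                           nAGQ = 0)
  co <- tidy(fit)
  truth <- c(1.0, log(0.65), log(1.2))
  expect_true(all(abs(co$estimate - truth) <= 2 * co$std_error))
})

test_that("z-scored and raw predictors give equivalent fixed effects", {
  set.seed(23)
  n <- 500
  x <- rnorm(n, mean = 10, sd = 3)
  y <- rbinom(n, 1, plogis(0.5 - 0.2 * x))
  fit_raw <- stats::glm(y ~ x, family = stats::binomial)
  z <- (x - mean(x)) / sd(x)
  fit_z <- stats::glm(y ~ z, family = stats::binomial)
  expect_equal(unname(coef(fit_z)[2]), unname(coef(fit_raw)[2]) * sd(x),
               tolerance = 1e-8)
})

test_that("likelihood ratio test behaves on nested fits", {
  sim <- make_comprehension_trials(
    n_participants = 30, n_items = 60,
    coefficients = c("(Intercept)" = 0.8, syllabic_rate = log(0.5),
                     motor_rate = 0),
    seed = 24)
  red <- fit_binomial_glmm(sim$trials, fixed = "motor_rate", nAGQ = 0)
  full <- fit_binomial_glmm(sim$trials,
                            fixed = c("motor_rate", "syllabic_rate"),
                            nAGQ = 0)
  lrt <- likelihood_ratio_test(red, full)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p_value, 0.001)
  expect_lt(full$aic, red$aic) # the generating predictor improves AIC

  self <- likelihood_ratio_test(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)
})

test_that("BH adjustment equals the step-up oracle", {
  ex <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(ex$reject))
  one <- fdr_adjust(0.03)
  expect_true(one$reject)
  expect_equal(one$p_fdr, 0.03)
  none <- fdr_adjust(rep(1, 6))
  expect_true(all(!none$reject))

  set.seed(25)
  grid <- c(0.001, 0.005, 0.01, 0.02, 0.04, 0.05, 0.1, 0.2, 0.5, 0.9, 1)
  for (i in 1:200) {
    p <- sample(grid, sample(1:10, 1), replace = TRUE)
    got <- fdr_adjust(p, q = 0.05)
    want <- bh_oracle(p, q = 0.05)
    expect_equal(got$p_fdr, want$adjusted, tolerance = 1e-12)
    expect_equal(got$reject, want$reject)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)),
               class = "speechsync_invalid_input")
})

test_that("rate accuracy summary gives Wilson intervals per condition", {
  d <- tibble::tibble(outcome = rep(1, 20), syllabic_rate = rep(5, 20))
  s <- rate_accuracy_summary(d)
  expect_equal(s$accuracy, 1)
  expect_true(s$ci_lower < 1 && s$ci_upper == 1)

  sim <- make_comprehension_trials(
    n_participants = 60, n_items = 120,
    coefficients = c("(Intercept)" = 1.7, syllabic_rate = log(0.65)),
    sd_participant = 0.2, sd_item = 0.1, sd_rate_slope = 0, seed = 26)
  s2 <- rate_accuracy_summary(sim$trials)
  expect_true(all(diff(s2$accuracy) < 0)) # monotone decline with rate
  expect_true(all(s2$accuracy >= s2$ci_lower &
                    s2$accuracy <= s2$ci_upper))
})
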