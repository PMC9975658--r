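#' Simulate two-interval forced-choice rate-preference trials
#'
#' Generates the full crossed 2IFC design (every reference rate against
#' every comparison rate, self-pairs included) for one participant whose
#' latent preference over syllabic rates is Gaussian,
#' \eqn{g(r) = \exp(-(r-\mathrm{peak})^2 / 2\sigma^2)} with
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}. On each trial the two
#' rates receive utilities \eqn{g(\cdot)} plus independent Gaussian decision
#' noise and the higher-utility rate is chosen; exact ties (including
#' noise-free self-pairs) are resolved by a fair coin.
#'
#' @param true_peak Latent preferred rate in syl/s (must lie inside the
#'   span of `rate_grid`).
#' @param true_fwhm Latent full width at half maximum in syl/s (`> 0`).
#' @param rate_grid Syllabic rates tested, default 3.00--8.50 syl/s in 7
#'   steps.
#' @param trials_per_pair Repetitions of each ordered (reference,
#'   comparison) pair (default 20).
#' @param decision_noise Standard deviation of the utility noise
#'   (default 0.7; 0 gives deterministic choices).
#' @param n_catch Number of catch (engagement) trials appended.
#' @param catch_accuracy Probability a catch trial is answered correctly.
#' @param participant Participant identifier stored in the table.
#' @param seed Integer seed.
#' @return A tibble with columns `participant`, `trial`, `rate_a`,
#'   `rate_b`, `choice` (the chosen rate; `NA` on catch trials),
#'   `is_catch`, `catch_correct`.
#' @export
make_2ifc_trials <- function(true_peak = 5.57, true_fwhm = 4.89,
                             rate_grid = c(3.00, 3.92, 4.83, 5.75,
                                           6.67, 7.58, 8.50),
                             trials_per_pair = 20, decision_noise = 0.7,
                             n_catch = 0, catch_accuracy = 0.985,
                             participant = 1L, seed = NULL) {
  if (length(rate_grid) < 2L) {
    stop_invalid("`rate_grid` needs at least 2 rates.")
  }
  check_number(true_peak, "true_peak",
               lower = min(rate_grid), upper = max(rate_grid))
  check_number(true_fwhm, "true_fwhm", lower = 1e-9)
  check_number(decision_noise, "decision_noise", lower = 0)
  check_count(trials_per_pair, "trials_per_pair", lower = 1L)
  check_count(n_catch, "n_catch")
  sigma <- true_fwhm / (2 * sqrt(2 * log(2)))
  g <- function(r) exp(-(r - true_peak)^2 / (2 * sigma^2))
  pairs <- tidyr::expand_grid(rate_a = rate_grid, rate_b = rate_grid)
  d <- tidyr::uncount(pairs, weights = trials_per_pair)
  with_seed(seed, {
    n <- nrow(d)
    ua <- g(d$rate_a) + if (decision_noise > 0) {
      rnorm(n, sd = decision_noise)
    } else 0
    ub <- g(d$rate_b) + if (decision_noise > 0) {
      rnorm(n, sd = decision_noise)
    } else 0
    choice <- ifelse(ua > ub, d$rate_a,
                     ifelse(ub > ua, d$rate_b,
                            ifelse(runif(n) < 0.5, d$rate_a, d$rate_b)))
    out <- tibble::tibble(
      participant = participant,
      trial = seq_len(n),
      rate_a = d$rate_a, rate_b = d$rate_b,
      choice = choice,
      is_catch = FALSE, catch_correct = NA
    )
    if (n_catch > 0) {
      catch <- tibble::tibble(
        participant = participant,
        trial = n + seq_len(n_catch),
        rate_a = NA_real_, rate_b = NA_real_, choice = NA_real_,
        is_catch = TRUE,
        catch_correct = runif(n_catch) < catch_accuracy
      )
      out <- dplyr::bind_rows(out, catch)
    }
    out
  })
}

#' Simulate binary comprehension trials from a known logistic model
#'
#' Generates trial-level word-order accuracy data from a logit-linear model
#' with crossed random intercepts (participant, item) and a by-participant
#' random slope for syllabic rate, so that the downstream mixed-model fit
#' can be checked against known truth.
#'
#' The design matrix is built from `names(coefficients)` (standard R
#' formula term syntax, interactions allowed). Item-level predictors
#' (`syllabic_rate`, `perplexity`, ...) and participant-level predictors
#' (`motor_rate`, `sync_group`, `working_memory`, ...) are drawn as
#' standardized covariates unless supplied through `participant_data` /
#' `item_data`, so each coefficient is a per-SD log-odds (its exponential a
#' per-SD odds ratio).
#'
#' @param n_participants,n_items Design size (`>= 2` each).
#' @param coefficients Named numeric vector of log-odds: must include
#'   `"(Intercept)"`; other names are formula terms over available
#'   covariates. Defaults mirror the effect pattern observed for
#'   comprehension of accelerated speech: odds falling with syllabic rate
#'   and perplexity, rising with motor rate, synchrony and working memory.
#' @param sd_participant,sd_item Random intercept SDs.
#' @param sd_rate_slope SD of the by-participant syllabic-rate slope.
#' @param participant_data Optional tibble of participant-level covariates
#'   (one row per participant, column `participant`).
#' @param item_data Optional tibble of item-level covariates (one row per
#'   item, column `item`).
#' @param seed Integer seed.
#' @return A list of class `comprehension_sim` with `trials` (tibble:
#'   `participant`, `item`, covariates, `p_true`, `outcome`) and `truth`
#'   (generating coefficients and SDs). `tidy()` returns the trial table.
#' @export
make_comprehension_trials <- function(
    n_participants = 82, n_items = 240,
    coefficients = c("(Intercept)" = 1.7,
                     syllabic_rate = log(0.65),
                     motor_rate = log(1.19),
                     sync_group = log(1.34),
                     working_memory = log(1.20),
                     perplexity = log(0.84)),
    sd_participant = 0.5, sd_item = 0.3, sd_rate_slope = 0.15,
    participant_data = NULL, item_data = NULL,
    seed = NULL) {
  check_count(n_participants, "n_participants", lower = 2L)
  check_count(n_items, "n_items", lower = 2L)
  if (is.null(names(coefficients)) || !"(Intercept)" %in% names(coefficients)) {
    stop_invalid("`coefficients` must be named and include \"(Intercept)\".")
  }
  if (any(!is.finite(coefficients))) {
    stop_invalid("All coefficients must be finite.")
  }
  check_number(sd_participant, "sd_participant", lower = 0)
  check_number(sd_item, "sd_item", lower = 0)
  check_number(sd_rate_slope, "sd_rate_slope", lower = 0)

  with_seed(seed, {
    pd <- participant_data %||% tibble::tibble(
      participant = seq_len(n_participants),
      motor_rate = rnorm(n_participants),
      sync_group = rbinom(n_participants, 1, 0.5),
      working_memory = rnorm(n_participants),
      preferred_rate = rnorm(n_participants)
    )
    id <- item_data %||% tibble::tibble(
      item = seq_len(n_items),
      syllabic_rate = as.numeric(scale(rep_len(
        c(5.00, 10.69, 12.48, 13.58, 14.38, 15.00), n_items))),
      perplexity = rnorm(n_items)
    )
    if (!"participant" %in% names(pd) || nrow(pd) != n_participants) {
      stop_invalid("`participant_data` needs `participant`, one row each.")
    }
    if (!"item" %in% names(id) || nrow(id) != n_items) {
      stop_invalid("`item_data` needs `item`, one row each.")
    }
    trials <- tidyr::expand_grid(participant = pd$participant,
                                 item = id$item) |>
      dplyr::left_join(pd, by = "participant") |>
      dplyr::left_join(id, by = "item")

    terms <- setdiff(names(coefficients), "(Intercept)")
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = trials)
    if (!all(colnames(X) %in% names(coefficients))) {
      stop_invalid(paste(
        "Design matrix columns lack coefficients:",
        paste(setdiff(colnames(X), names(coefficients)), collapse = ", ")))
    }
    if (qr(X)$rank < ncol(X)) {
      stop_invalid("Fixed-effects design matrix is rank deficient.")
    }
    eta <- drop(X %*% coefficients[colnames(X)])
    u_p <- setNames(rnorm(n_participants, 0, sd_participant),
                    pd$participant)
    u_i <- setNames(rnorm(n_items, 0, sd_item), id$item)
    s_p <- setNames(rnorm(n_participants, 0, sd_rate_slope),
                    pd$participant)
    rate <- if ("syllabic_rate" %in% names(trials)) {
      trials$syllabic_rate
    } else 0
    eta <- eta + u_p[as.character(trials$participant)] +
      u_i[as.character(trials$item)] +
      s_p[as.character(trials$participant)] * rate
    p <- plogis(eta)
    trials$p_true <- p
    trials$outcome <- rbinom(nrow(trials), 1, p)
    structure(
      list(
        trials = trials,
        truth = list(coefficients = coefficients,
                     sd_participant = sd_participant, sd_item = sd_item,
                     sd_rate_slope = sd_rate_slope)
      ),
      class = "comprehension_sim"
    )
  })
}

#' @export
print.comprehension_sim <- function(x, ...) {
  cat(sprintf(
    "<comprehension_sim: %d trials (%d participants x %d items), mean accuracy %.3f>\n",
    nrow(x$trials), dplyr::n_distinct(x$trials$participant),
    dplyr::n_distinct(x$trials$item), mean(x$trials$outcome)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.comprehension_sim <- function(x, ...) x$trials
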