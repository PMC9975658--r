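#' Configuration for the synthetic-cohort pipeline
#'
#' Bundles every tunable of the end-to-end demonstration with its default.
#' The configuration is a plain named list (JSON-serializable and
#' hashable), so runs are reproducible and identifiable by config hash +
#' seed.
#'
#' @param n_high,n_low Cohort composition (default 41 + 41).
#' @param sync_trials,sync_trial_s Synchronization runs per participant and
#'   their length (default 2 x 80 s).
#' @param plv_window_s,plv_overlap_s Windowed-PLV parameters (5 s / 2 s).
#' @param rate_trials,rate_trial_s,rate_fs Spontaneous-speech trials per
#'   participant, their length, and audio rate (default 2 x 30 s @ 4 kHz).
#' @param motor_rate_mean,motor_rate_sd Cohort distribution of the true
#'   articulation rate in syl/s (default 4.30 +/- 0.45).
#' @param pref_peak_mean,pref_peak_sd,pref_fwhm_mean,pref_fwhm_sd Cohort
#'   distribution of the latent preferred auditory rate and its FWHM
#'   (defaults 5.57 +/- 0.86 and 4.89 +/- 0.50 syl/s).
#' @param pref_trials_per_pair 2IFC repetitions per rate pair (default 10).
#' @param wm_mean,wm_sd Digit-span forward score distribution
#'   (default 8.46 +/- 2.12).
#' @param n_items Number of sentence items (default 240).
#' @param coefficients Generating fixed-effect log-odds for the
#'   comprehension model (per-SD scale).
#' @param sd_participant,sd_item,sd_rate_slope Generating random-effect
#'   SDs.
#' @param glmm_nAGQ Integrator order for the final mixed-model fit.
#' @return A `run_config` (named list).
#' @export
run_config <- function(n_high = 41, n_low = 41,
                       sync_trials = 2, sync_trial_s = 80,
                       plv_window_s = 5, plv_overlap_s = 2,
                       rate_trials = 2, rate_trial_s = 30, rate_fs = 4000,
                       motor_rate_mean = 4.30, motor_rate_sd = 0.45,
                       pref_peak_mean = 5.57, pref_peak_sd = 0.86,
                       pref_fwhm_mean = 4.89, pref_fwhm_sd = 0.50,
                       pref_trials_per_pair = 10,
                       wm_mean = 8.46, wm_sd = 2.12,
                       n_items = 240,
                       coefficients = c("(Intercept)" = 1.7,
                                        syllabic_rate = log(0.65),
                                        motor_rate = log(1.19),
                                        sync_group = log(1.34),
                                        working_memory = log(1.20),
                                        preferred_rate = log(1.14),
                                        perplexity = log(0.84),
                                        target1_prob = log(0.93),
                                        target2_prob = log(0.92),
                                        sentence_length = log(0.61),
                                        target_distance = log(1.48),
                                        compression = log(0.80)),
                       sd_participant = 0.5, sd_item = 0.3,
                       sd_rate_slope = 0.15,
                       glmm_nAGQ = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config: %d+%d participants, %d items, hash %s>\n",
              x$n_high, x$n_low, x$n_items, config_hash(x)))
  invisible(x)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

#' @rdname run_config
#' @param json A JSON string produced by `config_json()`.
#' @export
config_json <- function(config) {
  x <- unclass(config)
  x$coefficients <- as.list(x$coefficients) # keep names through JSON
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17))
}

#' @rdname run_config
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$coefficients <- unlist(x$coefficients)
  # JSON has no integer/double distinction; restore doubles throughout
  x <- lapply(x, function(v) if (is.integer(v)) as.numeric(v) else v)
  do.call(run_config, x)
}

# small built-in corpus for the n-gram provider used in the demo cohort
demo_corpus <- function() {
  c("the speaker reads a long sentence at a steady pace",
    "a listener follows the fast sentence with some effort",
    "the fast speech was hard to follow at the end",
    "syllables arrive at a steady rate in the long train",
    "the listener repeats the sentence after a short pause",
    "speech at a fast rate is hard for the listener",
    "a short sentence is easy to repeat at any rate",
    "the train of syllables keeps a steady fast pace",
    "some words in the sentence are hard to predict",
    "the speaker keeps a natural pace during the long reading")
}

#' Run the full synthetic-cohort analysis
#'
#' Generates a complete cohort with known ground truth and pushes it
#' through every analysis stage: phase-coupled stimulus/production pairs
#' -> windowed PLV -> k-means synchronizer classification; burst-structured
#' speech -> syllable-nuclei articulation rates; 2IFC trials -> Gaussian
#' preference fits; synthetic sentences -> n-gram perplexity and
#' target-word covariates; a logistic generative model of word-order
#' accuracy -> binomial-logit mixed model with odds ratios, FDR control,
#' likelihood-ratio model comparison and rate-binned accuracy. The result
#' bundles every stage's output plus a recovery report comparing estimates
#' to the generating truth.
#'
#' @param config A [run_config()].
#' @param seed Integer seed governing all randomness.
#' @return A `cohort_results` list: `participants`, `classification`,
#'   `items`, `trials`, `fit`, `fit_reduced`, `lrt`, `coefficients`
#'   (tidied, with `p_fdr`), `rate_accuracy`, `recovery`, `config_hash`,
#'   `seed`.
#' @export
run_synthetic_cohort <- function(config = run_config(), seed = 1L) {
  cfg <- config
  with_seed(seed, {
    ## --- auditory-motor synchronization -------------------------------
    pop <- make_population(
      n_high = cfg$n_high, n_low = cfg$n_low,
      trial_count = cfg$sync_trials, trial_duration = cfg$sync_trial_s)
    pop$plv <- vapply(pop$trials, function(trs) {
      participant_plv(lapply(trs, function(tr) {
        windowed_plv(tr$theta1, tr$theta2,
                     window_s = cfg$plv_window_s,
                     overlap_s = cfg$plv_overlap_s)
      }))
    }, numeric(1))
    cl <- classify_synchronizers(pop[c("participant", "plv")], seed = seed)
    labels <- tidy(cl)
    sync_agreement <- mean(labels$label == pop$label)

    ## --- spontaneous speech motor production rate ---------------------
    n_p <- nrow(pop)
    true_motor <- rnorm(n_p, cfg$motor_rate_mean, cfg$motor_rate_sd)
    rate_trials <- purrr::map(seq_len(n_p), function(i) {
      vapply(seq_len(cfg$rate_trials), function(j) {
        # one voiced stretch with a mid-trial pause, rate held at truth
        dur <- cfg$rate_trial_s
        pause <- c(dur * 0.45, dur * 0.45 + 1.5)
        voiced <- rbind(c(0, pause[1]), c(pause[2], dur))
        n_syl <- round(true_motor[i] * (dur - 1.5))
        sb <- make_speech_bursts(n_syl, voiced_segments = voiced,
                                 pause_segments = rbind(pause),
                                 fs = cfg$rate_fs, jitter_frac = 0.15)
        detect_syllable_nuclei(sb$audio)$articulation_rate
      }, numeric(1))
    })
    motor <- articulation_rate_cohort(tibble::tibble(
      participant = rep(pop$participant, each = cfg$rate_trials),
      rate = unlist(rate_trials)))

    ## --- preferred auditory rate --------------------------------------
    grid <- c(3.00, 3.92, 4.83, 5.75, 6.67, 7.58, 8.50)
    true_peak <- pmin(pmax(rnorm(n_p, cfg$pref_peak_mean, cfg$pref_peak_sd),
                           min(grid) + 0.1), max(grid) - 0.1)
    true_fwhm <- pmax(rnorm(n_p, cfg$pref_fwhm_mean, cfg$pref_fwhm_sd), 0.8)
    pref <- purrr::map_dfr(seq_len(n_p), function(i) {
      tr <- make_2ifc_trials(true_peak = true_peak[i],
                             true_fwhm = true_fwhm[i], rate_grid = grid,
                             trials_per_pair = cfg$pref_trials_per_pair,
                             participant = pop$participant[i])
      fit <- fit_gaussian_preference(build_preference_distribution(tr))
      tibble::tibble(participant = pop$participant[i],
                     preferred_rate = fit$peak, pref_fwhm = fit$fwhm)
    })

    ## --- working memory -----------------------------------------------
    wm <- pmin(pmax(round(rnorm(n_p, cfg$wm_mean, cfg$wm_sd)), 3), 15)

    ## --- linguistic predictability of the items -----------------------
    provider <- ngram_provider(demo_corpus(), order = 2, k = 0.5)
    vocab <- setdiff(attr(provider, "vocabulary"), "<oov>")
    sentences <- vapply(seq_len(cfg$n_items), function(i) {
      paste(sample(vocab, sample(6:12, 1), replace = TRUE),
            collapse = " ")
    }, character(1))
    n_tok <- lengths(tokenize(sentences))
    t1 <- vapply(n_tok, function(n) sample(seq_len(n - 2), 1), integer(1))
    t2 <- t1 + vapply(n_tok - t1, function(g) sample(seq_len(g), 1),
                      integer(1))
    pred <- score_predictability(sentences, provider,
                                 targets = cbind(t1, t2))
    exp2_rates <- c(5.00, 10.69, 12.48, 13.58, 14.38, 15.00)
    items <- tibble::tibble(
      item = seq_len(cfg$n_items),
      syllabic_rate = rep_len(exp2_rates, cfg$n_items),
      perplexity = pred$perplexity,
      target1_prob = pred$target1_prob,
      target2_prob = pred$target2_prob,
      sentence_length = n_tok,
      target_distance = t2 - t1,
      compression = rnorm(cfg$n_items)
    )

    ## --- comprehension trials from the generative logistic model ------
    zs <- function(x) as.numeric(scale(x))
    participants <- pop |>
      dplyr::select("participant", true_label = "label", "plv") |>
      dplyr::left_join(labels[c("participant", "label")],
                       by = "participant") |>
      dplyr::left_join(motor[c("participant", "motor_rate")],
                       by = "participant") |>
      dplyr::left_join(pref, by = "participant") |>
      dplyr::mutate(working_memory = wm,
                    sync_group = as.integer(.data$label == "HIGH"))
    pd <- participants |>
      dplyr::transmute(.data$participant,
                       motor_rate = zs(.data$motor_rate),
                       sync_group = .data$sync_group,
                       working_memory = zs(.data$working_memory),
                       preferred_rate = zs(.data$preferred_rate))
    id <- items |>
      dplyr::mutate(dplyr::across(-"item", zs))
    sim <- make_comprehension_trials(
      n_participants = n_p, n_items = cfg$n_items,
      coefficients = cfg$coefficients,
      sd_participant = cfg$sd_participant, sd_item = cfg$sd_item,
      sd_rate_slope = cfg$sd_rate_slope,
      participant_data = pd, item_data = id)

    ## --- inference -----------------------------------------------------
    continuous <- c("syllabic_rate", "motor_rate", "working_memory",
                    "preferred_rate", "perplexity", "target1_prob",
                    "target2_prob", "sentence_length", "target_distance",
                    "compression")
    tab <- build_predictor_table(sim$trials, z = continuous)
    linguistic <- c("perplexity", "target1_prob", "target2_prob",
                    "sentence_length", "target_distance", "compression")
    base_terms <- c("syllabic_rate", "motor_rate", "sync_group",
                    "working_memory", "preferred_rate")
    fit_reduced <- fit_binomial_glmm(tab, fixed = base_terms,
                                     nAGQ = cfg$glmm_nAGQ)
    fit <- fit_binomial_glmm(tab, fixed = c(base_terms, linguistic),
                             nAGQ = cfg$glmm_nAGQ)
    lrt <- likelihood_ratio_test(fit_reduced, fit)
    coefs <- tidy(fit)
    adj <- fdr_adjust(coefs$p_value[coefs$term != "(Intercept)"])
    coefs$p_fdr <- NA_real_
    coefs$p_fdr[coefs$term != "(Intercept)"] <- adj$p_fdr
    truth_tbl <- tibble::tibble(
      term = names(cfg$coefficients),
      true_log_odds = as.numeric(cfg$coefficients)
    )
    recovery <- coefs |>
      dplyr::left_join(truth_tbl, by = "term") |>
      dplyr::mutate(true_odds_ratio = exp(.data$true_log_odds),
                    within_2se = abs(.data$estimate - .data$true_log_odds) <=
                      2 * .data$std_error)

    structure(
      list(
        participants = participants,
        classification = cl,
        sync_agreement = sync_agreement,
        items = items,
        trials = sim$trials,
        fit = fit,
        fit_reduced = fit_reduced,
        lrt = lrt,
        coefficients = coefs,
        rate_accuracy = tab |>
          dplyr::left_join(
            dplyr::select(items, "item", rate_raw = "syllabic_rate"),
            by = "item") |>
          rate_accuracy_summary(rate = "rate_raw"),
        recovery = recovery,
        config_hash = config_hash(cfg),
        seed = seed
      ),
      class = "cohort_results"
    )
  })
}

#' @export
print.cohort_results <- function(x, ...) {
  g <- glance(x$classification)
  cat(sprintf("<cohort_results: %d participants, seed %d>\n",
              nrow(x$participants), x$seed))
  cat(sprintf("  PLV cluster centres: HIGH %.3f / LOW %.3f (label agreement %.1f%%)\n",
              g$center_high, g$center_low, 100 * x$sync_agreement))
  cat(sprintf("  motor rate: M = %.2f syl/s; preferred rate: M = %.2f syl/s\n",
              mean(x$participants$motor_rate, na.rm = TRUE),
              mean(x$participants$preferred_rate)))
  cat(sprintf("  GLMM: syllabic-rate OR %.2f; LRT for linguistic terms chi2 = %.1f (p = %.2g)\n",
              x$coefficients$odds_ratio[x$coefficients$term ==
                                          "syllabic_rate"],
              x$lrt$chi2, x$lrt$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_results <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.cohort_results <- function(x, ...) {
  g <- glance(x$classification)
  tibble::tibble(
    n_participants = nrow(x$participants),
    plv_center_high = g$center_high,
    plv_center_low = g$center_low,
    sync_agreement = x$sync_agreement,
    motor_rate_mean = mean(x$participants$motor_rate, na.rm = TRUE),
    preferred_rate_mean = mean(x$participants$preferred_rate),
    rate_or = x$coefficients$odds_ratio[x$coefficients$term ==
                                          "syllabic_rate"],
    lrt_chi2 = x$lrt$chi2,
    aic = x$fit$aic,
    seed = x$seed
  )
}
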