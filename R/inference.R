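#' Assemble the trial-level predictor table
#'
#' Joins trial outcomes with participant-level and item-level covariates on
#' unique keys, z-transforms the requested continuous predictors over the
#' analyzed trials (so every coefficient downstream is a per-SD log-odds),
#' and checks collinearity via variance inflation factors.
#'
#' @param trials Tibble with one row per trial, containing `participant`,
#'   `item`, the outcome column and any trial-level covariates.
#' @param participant_data Optional tibble keyed by `participant` (one row
#'   each) with participant-level covariates.
#' @param item_data Optional tibble keyed by `item` (one row each) with
#'   item-level covariates.
#' @param z Character vector of continuous predictor columns to z-score
#'   (mean 0, SD 1 over the analyzed trials). Defaults to none.
#' @param vif_bound Error if any modeled continuous predictor's VIF is not
#'   below this bound (default `Inf`, i.e. report only).
#' @return A tibble with attribute `"vif"` (named VIFs over the z-scored
#'   columns, when 2 or more) and `"z_scaling"` (means/SDs used).
#' @export
build_predictor_table <- function(trials, participant_data = NULL,
                                  item_data = NULL, z = character(),
                                  vif_bound = Inf) {
  if (!all(c("participant", "item") %in% names(trials))) {
    stop_invalid_input("`trials` needs `participant` and `item` columns.")
  }
  out <- trials
  if (!is.null(participant_data)) {
    if (anyDuplicated(participant_data$participant)) {
      stop_invalid_input("`participant_data` has duplicated participants.")
    }
    missing_p <- setdiff(unique(out$participant),
                         participant_data$participant)
    if (length(missing_p) > 0) {
      stop_invalid_input(paste("Participants missing covariates:",
                               paste(head(missing_p, 5), collapse = ", ")))
    }
    out <- dplyr::left_join(out, participant_data, by = "participant")
  }
  if (!is.null(item_data)) {
    if (anyDuplicated(item_data$item)) {
      stop_invalid_input("`item_data` has duplicated items.")
    }
    missing_i <- setdiff(unique(out$item), item_data$item)
    if (length(missing_i) > 0) {
      stop_invalid_input(paste("Items missing covariates:",
                               paste(head(missing_i, 5), collapse = ", ")))
    }
    out <- dplyr::left_join(out, item_data, by = "item")
  }
  z <- intersect(z, names(out))
  scaling <- NULL
  if (length(z) > 0) {
    if (any(!complete.cases(out[z]))) {
      stop_invalid_input("Missing values in predictors marked for z-scoring.")
    }
    scaling <- tibble::tibble(
      column = z,
      mean = vapply(out[z], mean, numeric(1)),
      sd = vapply(out[z], sd, numeric(1))
    )
    if (any(scaling$sd == 0)) {
      stop_invalid_input(paste("Zero-variance predictor:",
                               scaling$column[scaling$sd == 0][1]))
    }
    for (i in seq_along(z)) {
      out[[z[i]]] <- (out[[z[i]]] - scaling$mean[i]) / scaling$sd[i]
    }
    if (length(z) >= 2) {
      v <- vif(out[z])
      attr(out, "vif") <- v
      if (any(!is.finite(v)) || any(v >= vif_bound)) {
        stop_invalid_input(paste(
          "Variance inflation above bound for:",
          paste(names(v)[!is.finite(v) | v >= vif_bound], collapse = ", ")))
      }
    }
  }
  attr(out, "z_scaling") <- scaling
  out
}

#' Variance inflation factors of a set of continuous predictors
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} is from regressing
#' predictor j on all others. Orthogonal predictors give 1; perfectly
#' collinear ones give `Inf`.
#'
#' @param x A data frame or matrix of numeric predictors (2+ columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2) stop_invalid_input("VIF needs at least 2 predictors.")
  r <- stats::cor(m)
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(inv)) {
    v <- rep(Inf, ncol(m))
  } else {
    v <- diag(inv)
    v[v < 1] <- 1 # numerical guard; VIF >= 1 by construction
  }
  setNames(as.numeric(v), colnames(m))
}

#' Fit the binomial-logit mixed model for trial-level comprehension
#'
#' Fits `outcome ~ fixed effects + (1 + rate | participant) + (1 | item)`
#' by maximum likelihood with a binomial logit link (delegating the
#' mixed-model machinery to \pkg{lme4}), and reports, per fixed effect, the
#' log-odds estimate, standard error, odds ratio (`exp(estimate)`), Wald z
#' p-value, plus AIC, log-likelihood and random-effect SDs. If the full
#' random-effects structure fails to converge, the fit falls back to
#' random intercepts only, with a warning.
#'
#' @param data Trial-level tibble (e.g. from [build_predictor_table()]).
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @param fixed Character vector of fixed-effect terms.
#' @param rate_slope Name of the predictor given a by-participant random
#'   slope (`NULL` for intercepts only). Default `"syllabic_rate"` when
#'   present.
#' @param correlated_slope Estimate the slope-intercept correlation
#'   (default `FALSE`, i.e. `||` syntax).
#' @param nAGQ Integrator order passed to \pkg{lme4}: 1 (Laplace; default)
#'   or 0 (faster, optimizes into the penalized weighted RSS; used for
#'   large simulation studies).
#' @return A `comprehension_fit`; `tidy()` returns the coefficient table
#'   (`term`, `estimate`, `std_error`, `odds_ratio`, `statistic`,
#'   `p_value`), `glance()` model-level summaries.
#' @export
fit_binomial_glmm <- function(data, outcome = "outcome",
                              fixed,
                              rate_slope = if ("syllabic_rate" %in%
                                               names(data)) {
                                "syllabic_rate"
                              } else {
                                NULL
                              },
                              correlated_slope = FALSE,
                              nAGQ = 1) {
  if (!outcome %in% names(data)) {
    stop_invalid_input(sprintf("Outcome column `%s` not found.", outcome))
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) {
    stop_invalid_input("Outcome must be binary (0/1).")
  }
  missing_fixed <- setdiff(all.vars(stats::as.formula(
    paste("~", paste(fixed, collapse = "+")))), names(data))
  if (length(missing_fixed) > 0) {
    stop_invalid_input(paste("Fixed-effect columns not found:",
                             paste(missing_fixed, collapse = ", ")))
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fixed, collapse = "+"))), data)
  if (qr(X)$rank < ncol(X)) {
    stop_invalid_input("Fixed-effects design is rank deficient.")
  }
  re_full <- if (!is.null(rate_slope)) {
    sprintf("(1 %s %s %s participant) + (1 | item)",
            if (correlated_slope) "+" else "+",
            rate_slope, if (correlated_slope) "|" else "||")
  } else {
    "(1 | participant) + (1 | item)"
  }
  fml <- stats::as.formula(paste(
    outcome, "~", paste(fixed, collapse = " + "), "+", re_full))
  ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                             check.conv.singular = "ignore")
  fit <- tryCatch(
    suppressMessages(lme4::glmer(fml, data = data, family = stats::binomial,
                                 nAGQ = nAGQ, control = ctrl)),
    error = function(e) e, warning = function(w) w
  )
  converged <- !inherits(fit, "condition")
  if (!converged && !is.null(rate_slope)) {
    rlang::warn(paste(
      "Full random-effects model did not converge;",
      "refitting with random intercepts only."))
    fml <- stats::as.formula(paste(
      outcome, "~", paste(fixed, collapse = " + "),
      "+ (1 | participant) + (1 | item)"))
    fit <- suppressMessages(lme4::glmer(fml, data = data,
                                        family = stats::binomial,
                                        nAGQ = nAGQ, control = ctrl))
    converged <- TRUE
  } else if (!converged) {
    rlang::abort(paste("Mixed model failed:", conditionMessage(fit)),
                 class = c("speechsync_fit_failure", "speechsync_error"))
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zval <- est / se
  coefs <- tibble::tibble(
    term = names(est),
    estimate = as.numeric(est),
    std_error = as.numeric(se),
    odds_ratio = exp(as.numeric(est)),
    statistic = as.numeric(zval),
    p_value = 2 * pnorm(-abs(as.numeric(zval)))
  )
  vc <- lme4::VarCorr(fit)
  re_sds <- unlist(lapply(vc, function(v) attr(v, "stddev")))
  structure(
    list(
      coefficients = coefs,
      formula = fml,
      log_likelihood = as.numeric(logLik(fit)),
      df = attr(logLik(fit), "df"),
      aic = AIC(fit),
      n_obs = nrow(data),
      random_effect_sds = re_sds,
      converged = converged,
      model = fit
    ),
    class = "comprehension_fit"
  )
}

#' @export
print.comprehension_fit <- function(x, ...) {
  cat(sprintf("<comprehension_fit: %d obs, logLik %.1f, AIC %.1f>\n",
              x$n_obs, x$log_likelihood, x$aic))
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.comprehension_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.comprehension_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, df = x$df,
    log_likelihood = x$log_likelihood, aic = x$aic,
    converged = x$converged
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.comprehension_fit <- function(object, ...) {
  d <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  d$lo <- exp(d$estimate - 1.96 * d$std_error)
  d$hi <- exp(d$estimate + 1.96 * d$std_error)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio,
                                  y = stats::reorder(.data$term,
                                                     .data$odds_ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% Wald CI)", y = NULL)
}

#' Likelihood ratio test between nested model fits
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} on degrees of freedom
#' equal to the parameter-count difference.
#'
#' @param fit_reduced,fit_full `comprehension_fit` objects on the same
#'   data, reduced nested in full.
#' @return A one-row tibble: `chi2`, `df`, `p_value`, and the two AICs.
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_full) {
  if (!inherits(fit_reduced, "comprehension_fit") ||
      !inherits(fit_full, "comprehension_fit")) {
    stop_invalid_input("Both arguments must be comprehension_fit objects.")
  }
  if (fit_reduced$n_obs != fit_full$n_obs) {
    stop_invalid_input("Models were fitted to different numbers of trials.")
  }
  df <- fit_full$df - fit_reduced$df
  if (df < 0) {
    stop_invalid_input("`fit_full` has fewer parameters than `fit_reduced`.")
  }
  chi2 <- max(0, 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood))
  tibble::tibble(
    chi2 = chi2, df = df,
    p_value = if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE),
    aic_reduced = fit_reduced$aic, aic_full = fit_full$aic
  )
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment of a vector of p-values; rejection flags at level
#' `q` and monotone adjusted p-values.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A tibble: `p_value`, `p_fdr`, `reject`, in the input order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop_invalid_input("All p-values must lie in [0, 1].")
  }
  check_number(q, "q", lower = 0, upper = 1)
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_fdr = adj, reject = adj <= q)
}

#' Accuracy by syllabic-rate condition
#'
#' Binomial proportion of correct responses per rate condition with Wilson
#' 95% confidence intervals — the descriptive rate-response profile.
#'
#' @param data Trial tibble with the outcome and rate columns.
#' @param outcome,rate Column names (defaults `"outcome"`,
#'   `"syllabic_rate"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `rate`, `n`, `accuracy`, `ci_lower`, `ci_upper`.
#' @export
rate_accuracy_summary <- function(data, outcome = "outcome",
                                  rate = "syllabic_rate",
                                  conf_level = 0.95) {
  if (!all(c(outcome, rate) %in% names(data))) {
    stop_invalid_input("Outcome or rate column not found.")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  data |>
    dplyr::group_by(rate = .data[[rate]]) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = mean(.data[[outcome]]),
                     .groups = "drop") |>
    dplyr::mutate(
      centre = (.data$accuracy + z^2 / (2 * .data$n)) /
        (1 + z^2 / .data$n),
      half = z * sqrt(.data$accuracy * (1 - .data$accuracy) / .data$n +
                        z^2 / (4 * .data$n^2)) / (1 + z^2 / .data$n),
      ci_lower = pmax(0, .data$centre - .data$half),
      ci_upper = pmin(1, .data$centre + .data$half)
    ) |>
    dplyr::select("rate", "n", "accuracy", "ci_lower", "ci_upper")
}
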