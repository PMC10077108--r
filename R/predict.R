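# vectorized empirical-Bayes update for every subject in a baseline table:
# condition (b0, b1) ~ N(0, G) on the single baseline eGFR residual
posterior_table <- function(model, baseline) {
  preds <- model$spec$predictors
  miss <- setdiff(c(preds, "baseline_egfr", "country"), names(baseline))
  if (length(miss) > 0) {
    abort(paste0("schema error: baseline table missing: ",
                 paste(miss, collapse = ", ")))
  }
  P <- as.matrix(baseline[preds])
  beta <- model$beta
  x0b <- beta[["(Intercept)"]] + drop(P %*% beta[preds])
  known <- baseline$country %in% names(model$country_effects)
  u_c <- unname(ifelse(known, model$country_effects[baseline$country], 0))
  s2 <- model$sigma2 + ifelse(known, 0, model$tau2)
  G <- model$G
  denom <- G[1, 1] + s2
  r <- baseline$baseline_egfr - (x0b + u_c)
  tibble(
    subject_id = baseline$subject_id,
    country = baseline$country,
    residual = r,
    b0 = G[1, 1] * r / denom,
    b1 = G[2, 1] * r / denom,
    v00 = G[1, 1] - G[1, 1]^2 / denom,
    v01 = G[1, 2] - G[1, 1] * G[1, 2] / denom,
    v11 = G[2, 2] - G[1, 2]^2 / denom,
    country_effect = u_c,
    country_known = known,
    fixed_baseline = x0b + u_c
  )
}

#' Update a new individual's random effects from their baseline eGFR
#'
#' Empirical-Bayes (BLUP) conditioning of the individual random effects
#' \eqn{(b_0, b_1) \sim N(0, G)} on the single baseline eGFR measurement:
#' with observation vector `z = (1, 0)` and residual
#' `r = y0 - x0'beta - u_country`,
#' \deqn{mean = G z (z'Gz + s^2)^{-1} r, \quad
#'       cov = G - G z (z'Gz + s^2)^{-1} z'G}
#' where \eqn{s^2 = \sigma^2}, plus \eqn{\tau^2} folded into the
#' conditioning noise when the subject's country was not part of training
#' (the country effect is then taken as 0, with a message).
#'
#' @param model A fitted `egfr_lmm`.
#' @param subject One-row baseline tibble with the model predictors,
#'   `country` and `baseline_egfr`.
#' @return Object of class `egfr_posterior`: `mean` (length-2), `cov`
#'   (2x2), `country_effect`, `country_known`, `residual`.
#' @export
update_random_effects <- function(model, subject) {
  if (nrow(subject) != 1) abort("subject must be a single baseline row")
  if (!"baseline_egfr" %in% names(subject) || is.na(subject$baseline_egfr)) {
    abort("precondition error: subject lacks a baseline eGFR")
  }
  pt <- posterior_table(model, subject)
  if (!pt$country_known) {
    inform(sprintf(
      "country '%s' not in training data: using country effect 0 with widened variance",
      subject$country))
  }
  structure(
    list(mean = c(b0 = pt$b0, b1 = pt$b1),
         cov = matrix(c(pt$v00, pt$v01, pt$v01, pt$v11), 2, 2,
                      dimnames = list(c("b0", "b1"), c("b0", "b1"))),
         country_effect = pt$country_effect,
         country_known = pt$country_known,
         residual = pt$residual),
    class = "egfr_posterior"
  )
}

#' @export
print.egfr_posterior <- function(x, ...) {
  cat("<egfr_posterior> mean (b0, b1):", format(x$mean, digits = 4), "\n")
  cat("  sd:", format(sqrt(diag(x$cov)), digits = 4),
      " country effect:", format(x$country_effect, digits = 4),
      if (!x$country_known) "(new country)", "\n")
  invisible(x)
}

# fixed-effect design row(s) for one subject at given times
subject_design_rows <- function(model, subject, times) {
  spec <- model$spec
  x <- matrix(0, length(times), length(model$col_names),
              dimnames = list(NULL, model$col_names))
  x[, "(Intercept)"] <- 1
  for (p in spec$predictors) x[, p] <- subject[[p]]
  x[, "time"] <- times
  for (p in spec$interactions) x[, paste0(p, ":time")] <- subject[[p]] * times
  x
}

#' Predict an individual's eGFR trajectory
#'
#' Point predictions and predictive SDs of eGFR at the requested times:
#' `yhat(t) = x(t)'beta + u_country + b0 + b1 t`, with predictive variance
#' `(1, t) cov (1, t)' + sigma^2` (the posterior random-effect uncertainty
#' plus measurement noise), optionally plus the fixed-effect estimation
#' term `x(t)' cov(beta) x(t)`. Times beyond the horizon (5 years by
#' default, the span over which the model is considered reliable) are
#' flagged and warned about, not refused.
#'
#' @param model A fitted `egfr_lmm`.
#' @param subject One-row baseline tibble.
#' @param times Prediction times in years (>= 0).
#' @param posterior Optional [update_random_effects()] result; computed
#'   from the subject's baseline eGFR when `NULL`. Pass `FALSE` to predict
#'   without updating (population-level prediction).
#' @param include_beta_uncertainty Add fixed-effect estimation variance.
#' @param horizon Extrapolation warning threshold in years (default 5).
#' @param conf_level Level of the normal predictive interval.
#' @return Tibble with `time`, `egfr_pred`, `pred_sd`, `pred_lo`,
#'   `pred_hi`, `extrapolated`.
#' @export
predict_trajectory <- function(model, subject, times, posterior = NULL,
                               include_beta_uncertainty = FALSE,
                               horizon = 5, conf_level = 0.95) {
  if (any(times < 0)) abort("prediction times must be >= 0")
  if (nrow(subject) != 1) abort("subject must be a single baseline row")
  no_update <- isFALSE(posterior)
  if (is.null(posterior) || no_update) {
    post <- if (no_update) NULL else update_random_effects(model, subject)
  } else {
    post <- posterior
  }
  if (any(times > horizon)) {
    warn(sprintf("prediction beyond the %g-year horizon is extrapolation", horizon))
  }
  x <- subject_design_rows(model, subject, times)
  if (is.null(post)) {
    known <- subject$country %in% names(model$country_effects)
    u_c <- if (known) model$country_effects[[subject$country]] else 0
    b <- c(0, 0)
    vpost <- model$G
    extra_tau <- if (known) 0 else model$tau2
  } else {
    u_c <- post$country_effect
    b <- post$mean
    vpost <- post$cov
    extra_tau <- if (post$country_known) 0 else model$tau2
  }
  b <- as.numeric(b)
  u_c <- as.numeric(u_c)
  pred <- drop(x %*% model$beta) + u_c + b[1] + b[2] * times
  vr <- vpost[1, 1] + 2 * vpost[1, 2] * times + vpost[2, 2] * times^2 +
    model$sigma2 + extra_tau
  if (include_beta_uncertainty) {
    vr <- vr + rowSums((x %*% model$beta_cov) * x)
  }
  zc <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    time = times, egfr_pred = pred, pred_sd = sqrt(vr),
    pred_lo = pred - zc * sqrt(vr), pred_hi = pred + zc * sqrt(vr),
    extrapolated = times > horizon
  )
}

#' Distribution of an individual's eGFR slope
#'
#' The derivative of the model equation with respect to time, evaluated at
#' the subject's covariates, plus the posterior random slope:
#' `mean = beta_t + x'gamma + b1_hat` (eGFR per year). The default
#' variance is the posterior random-slope variance; fixed-effect
#' estimation uncertainty of the time block can be added.
#'
#' @inheritParams predict_trajectory
#' @param posterior An [update_random_effects()] result; computed when
#'   `NULL`.
#' @return Object of class `egfr_slope`: `mean`, `sd`, `components`
#'   (fixed part and posterior random part).
#' @export
slope_distribution <- function(model, subject, posterior = NULL,
                               include_beta_uncertainty = FALSE) {
  if (nrow(subject) != 1) abort("subject must be a single baseline row")
  if (is.null(posterior)) posterior <- update_random_effects(model, subject)
  spec <- model$spec
  xi <- purrr::map_dbl(spec$interactions, ~ subject[[.x]])
  gam <- model$beta[paste0(spec$interactions, ":time")]
  fixed_part <- model$beta[["time"]] + sum(xi * gam)
  vr <- posterior$cov[2, 2]
  if (include_beta_uncertainty) {
    tcols <- c("time", paste0(spec$interactions, ":time"))
    xt <- c(1, xi)
    vr <- vr + drop(xt %*% model$beta_cov[tcols, tcols] %*% xt)
  }
  structure(
    list(mean = fixed_part + posterior$mean[["b1"]],
         sd = sqrt(vr),
         components = tibble(fixed_part = fixed_part,
                             random_part = posterior$mean[["b1"]],
                             var_posterior_slope = posterior$cov[2, 2])),
    class = "egfr_slope"
  )
}

#' @export
print.egfr_slope <- function(x, ...) {
  cat("<egfr_slope> mean:", format(x$mean, digits = 4),
      "eGFR/yr, sd:", format(x$sd, digits = 4), "\n")
  invisible(x)
}

#' Probability of rapid CKD progression
#'
#' Value of the predictive (normal) distribution function of the
#' individual eGFR slope at the rapid-progression threshold,
#' `Phi((threshold - mean) / sd)`; with a degenerate slope distribution
#' (`sd = 0`) it is the indicator `mean < threshold`. The default
#' threshold of -3 mL/min/1.73 m^2 per year separates stable from rapid
#' progression.
#'
#' @param slope An `egfr_slope` object, or a numeric slope mean.
#' @param sd Slope SD when `slope` is numeric.
#' @param threshold Rapid-progression threshold in eGFR/yr (default -3).
#' @return Probability in `[0, 1]`.
#' @export
prob_rapid_progression <- function(slope, sd = NULL, threshold = -3) {
  if (inherits(slope, "egfr_slope")) {
    m <- slope$mean; s <- slope$sd
  } else {
    m <- slope; s <- sd
    if (is.null(s)) abort("sd must be supplied with a numeric slope mean")
  }
  if (any(s < 0)) abort("slope sd must be >= 0")
  ifelse(s == 0, as.numeric(m < threshold), pnorm((threshold - m) / s))
}

#' Per-subject slope and rapid-progression summary for a cohort
#'
#' Vectorized over a baseline table: empirical-Bayes update from each
#' subject's baseline eGFR, individual slope mean/SD, and the probability
#' of rapid progression at the given threshold.
#'
#' @param model A fitted `egfr_lmm`.
#' @param baseline Baseline tibble.
#' @param threshold Rapid-progression threshold (default -3 eGFR/yr).
#' @return Tibble with `subject_id`, `country`, `slope_mean`, `slope_sd`,
#'   `prob_rapid`.
#' @export
rapid_progression_table <- function(model, baseline, threshold = -3) {
  post <- posterior_table(model, baseline)
  spec <- model$spec
  gam <- model$beta[paste0(spec$interactions, ":time")]
  XI <- as.matrix(baseline[spec$interactions])
  fixed_part <- model$beta[["time"]] + drop(XI %*% gam)
  slope_mean <- fixed_part + post$b1
  slope_sd <- sqrt(post$v11)
  tibble(
    subject_id = baseline$subject_id,
    country = baseline$country,
    slope_mean = slope_mean,
    slope_sd = slope_sd,
    prob_rapid = prob_rapid_progression(slope_mean, slope_sd, threshold)
  )
}
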