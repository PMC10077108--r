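#' Marginal and conditional R2 of the fitted trajectory model
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional), computed from the variance budget
#' \eqn{var(X\hat\beta) / (var(X\hat\beta) + \bar{z G z'} + \tau^2 +
#' \sigma^2)}; the random-slope contribution \eqn{\bar{z G z'}} is the
#' design-averaged value of \eqn{(1, t) G (1, t)'} over all visit rows.
#'
#' @param fit An `egfr_lmm` fit (must have converged).
#' @param design Optional `egfr_design`; defaults to the one stored in the
#'   fit.
#' @return One-row tibble with `r2_marginal`, `r2_conditional` and the
#'   variance components of the budget.
#' @export
r2_nakagawa <- function(fit, design = fit$design) {
  if (!isTRUE(fit$converged)) abort("model fit did not converge")
  xb <- as.numeric(design$X %*% fit$beta)
  var_fixed <- mean((xb - mean(xb))^2)
  zgz <- fit$G[1, 1] + 2 * fit$G[1, 2] * design$time +
    fit$G[2, 2] * design$time^2
  var_random <- mean(zgz) + fit$tau2
  total <- var_fixed + var_random + fit$sigma2
  if (total <= 0) abort("undefined-ratio error: zero total variance")
  tibble(
    r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + var_random) / total,
    var_fixed = var_fixed, var_random = var_random, var_residual = fit$sigma2
  )
}

#' Standardized coefficient report
#'
#' Rescales the fixed-effect estimates for reporting: coefficients of
#' continuous predictors (mains and their time interactions) are multiplied
#' by the predictor's training-sample SD, so they read as eGFR difference
#' per 1-SD difference in the predictor; binary predictors are left on
#' their natural 0/1 scale. The intercept and the time main effect are
#' reported unscaled. Wald 95% CIs are transformed alongside.
#'
#' @param fit An `egfr_lmm` fit.
#' @param conf_level Confidence level.
#' @return Tibble with `term`, `predictor`, `type` (main/interaction/other),
#'   `estimate` (raw), `std.error`, `scale` (SD used, 1 for binary),
#'   `standardized`, `conf.low`, `conf.high` (standardized scale).
#' @export
standardized_coefficients <- function(fit, conf_level = 0.95) {
  sds <- fit$predictor_sds
  if (any(sds == 0)) {
    abort(paste0("degenerate-predictor error: zero SD for ",
                 paste(names(sds)[sds == 0], collapse = ", ")))
  }
  td <- tidy(fit, conf_level = conf_level)
  base <- sub(":time$", "", td$term)
  td$predictor <- ifelse(base %in% fit$spec$predictors, base, NA_character_)
  td$type <- dplyr::case_when(
    td$term %in% fit$spec$predictors ~ "main",
    grepl(":time$", td$term) & !is.na(td$predictor) ~ "interaction",
    TRUE ~ "other"
  )
  td$scale <- ifelse(!is.na(td$predictor) & td$predictor %in% names(sds),
                     sds[td$predictor], 1)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  td$standardized <- td$estimate * td$scale
  td$conf.low <- td$standardized - zc * td$std.error * td$scale
  td$conf.high <- td$standardized + zc * td$std.error * td$scale
  td %>% select(all_of(c("term", "predictor", "type", "estimate", "std.error",
                         "scale", "standardized", "conf.low", "conf.high")))
}

#' Predictor importance by drop-one marginal R2
#'
#' Refits the model without one predictor (its main effect and its time
#' interaction) and returns the decrease in marginal R2 relative to the
#' full fit. Both models' fixed-effect variances are referenced to the
#' full model's variance budget, so importances are directly comparable
#' across predictors and nonnegative (up to numerical tolerance) for
#' predictors that carry no information.
#'
#' @param fit An `egfr_lmm` fit holding its training data.
#' @param predictors Predictors to drop, one at a time; defaults to all.
#' @return Tibble with `predictor`, `r2_marginal_full`,
#'   `r2_marginal_reduced`, `delta_marginal_r2`, sorted by decreasing
#'   importance.
#' @export
drop_one_marginal_r2 <- function(fit, predictors = fit$spec$predictors) {
  bad <- setdiff(predictors, fit$spec$predictors)
  if (length(bad) > 0) {
    abort(paste0("unknown predictor(s): ", paste(bad, collapse = ", ")))
  }
  if (is.null(fit$baseline)) {
    abort("fit does not hold training data (loaded from JSON?); refit required")
  }
  full <- r2_nakagawa(fit)
  total <- full$var_fixed + full$var_random + full$var_residual
  res <- purrr::map_dfr(predictors, function(p) {
    spec_red <- egfr_model_spec(
      predictors = setdiff(fit$spec$predictors, p),
      time_name = fit$spec$time_name,
      interactions = setdiff(fit$spec$interactions, p),
      method = fit$spec$method
    )
    fit_red <- fit_egfr_lmm(fit$baseline, fit$visits, spec_red)
    tibble(predictor = p,
           r2_marginal_full = full$r2_marginal,
           r2_marginal_reduced = r2_nakagawa(fit_red)$var_fixed / total)
  })
  res$delta_marginal_r2 <- res$r2_marginal_full - res$r2_marginal_reduced
  res %>% arrange(dplyr::desc(.data$delta_marginal_r2))
}
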