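# Shared fixtures and independent oracles for the test suite.

# Exchangeable three-country configuration: country heterogeneity only via
# u_c ~ N(0, tau2); well-specified for the fitted model.
exchangeable_config <- function(n_per_country = 100, seed = 1, ...) {
  sim_config(n_per_country = n_per_country, target_baseline_egfr = NULL,
             seed = seed, ...)
}

# Noise-free degenerate configuration: all covariates identically zero,
# no random effects, intercept 90, slope -1 per year.
degenerate_config <- function(n_per_country = 5, seed = 1, sigma2 = 0,
                              schedule = list(0:3)) {
  fx <- default_true_effects()
  fx[] <- 0
  fx["(Intercept)"] <- 90
  fx["time"] <- -1
  zero_cov <- tidyr::expand_grid(
    country = "z", predictor = egfr_predictors()
  ) |>
    dplyr::mutate(type = "normal", mean = 0, sd = 0, prob = NA_real_,
                  lower = NA_real_, upper = NA_real_)
  sim_config(
    n_per_country = n_per_country,
    countries = tibble::tibble(country = "z", schedule = schedule),
    true_effects = fx, G_true = matrix(0, 2, 2), tau2_true = 0,
    sigma2_true = sigma2, covariates = zero_cov,
    target_baseline_egfr = NULL, visit_jitter_sd = 0, dropout_rate = 0,
    seed = seed
  )
}

# Memoized medium-size fitted model shared across test files in one run.
.fixture_env <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- exchangeable_config(n_per_country = 80, seed = 424)
    coh <- simulate_cohort(cfg)
    .fixture_env$cohort <- c(
      apply_inclusion_filters(coh$baseline, coh$visits)[c("baseline", "visits")],
      list(truth = coh$truth, config = cfg)
    )
  }
  .fixture_env$cohort
}
shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ch <- shared_cohort()
    .fixture_env$fit <- fit_egfr_lmm(ch$baseline, ch$visits)
  }
  .fixture_env$fit
}

# Minimal model object for closed-form prediction tests: given variance
# components and fixed effects, with a single known country of effect 0.
toy_model <- function(G, sigma2, tau2 = 0,
                      beta = NULL, country_effects = c(z = 0)) {
  spec <- egfr_model_spec()
  cn <- c("(Intercept)", spec$predictors, "time",
          paste0(spec$interactions, ":time"))
  if (is.null(beta)) beta <- setNames(rep(0, length(cn)), cn)
  structure(
    list(beta = beta, beta_cov = diag(0, length(cn)), G = G, tau2 = tau2,
         sigma2 = sigma2, country_effects = country_effects,
         predictor_sds = NULL, col_names = cn, spec = spec,
         converged = TRUE, method = "REML"),
    class = "egfr_lmm"
  )
}

# one-row baseline tibble with all predictors zero
toy_subject <- function(baseline_egfr, country = "z") {
  vals <- as.list(setNames(rep(0, length(egfr_predictors())),
                           egfr_predictors()))
  tibble::tibble(subject_id = "s1", country = country, !!!vals,
                 uacr = 1, baseline_egfr = baseline_egfr)
}

# Independent oracle: condition (b0, b1) on y0 by forming the joint
# 3x3 normal covariance and conditioning numerically with solve().
condition_oracle <- function(G, s2, r) {
  z <- c(1, 0)
  S11 <- G
  S12 <- G %*% z
  S22 <- drop(t(z) %*% G %*% z) + s2
  mean <- drop(S12 %*% solve(S22) * r)
  cov <- S11 - S12 %*% solve(S22) %*% t(S12)
  list(mean = mean, cov = cov)
}

# Independent oracle: exhaustive pair enumeration for the C statistic.
c_statistic_brute <- function(obs, pred) {
  n <- length(obs)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (obs[i] == obs[j]) next
      den <- den + 1
      dp <- pred[i] - pred[j]
      if (dp == 0) num <- num + 0.5
      else if (sign(dp) == sign(obs[i] - obs[j])) num <- num + 1
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

rmse <- function(x) sqrt(mean(x^2))
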