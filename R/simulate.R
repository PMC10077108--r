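#' Canonical baseline predictor set
#'
#' The twelve baseline predictors of the eGFR trajectory model, in the
#' canonical column order used throughout the package: age (years), sex
#' (0 = female, 1 = male), body-mass index (kg/m^2), ever-smoker indicator,
#' HbA1c (mmol/mol), hemoglobin (g/dL), serum cholesterol (mg/dL), mean
#' arterial pressure (mm Hg), log2 urinary albumin-creatinine ratio
#' (log2 mg/g), and indicators for glucose-, blood-pressure- and
#' lipid-lowering medication. Time since baseline (years) enters the model
#' separately, both as a main effect and in interaction with each predictor.
#'
#' @return Character vector of length 12.
#' @export
egfr_predictors <- function() {
  c("age", "sex", "bmi", "smoking_ever", "hba1c", "hemoglobin",
    "cholesterol", "map", "log2_uacr", "med_glucose", "med_bp", "med_lipid")
}

#' Which canonical predictors are binary
#' @return Character vector, subset of [egfr_predictors()].
#' @export
egfr_binary_predictors <- function() {
  c("sex", "smoking_ever", "med_glucose", "med_bp", "med_lipid")
}

#' Default per-country covariate generating laws
#'
#' Calibrated to the published cohort descriptives of three European
#' type-2-diabetes CKD cohorts: a low-eGFR biennial-visit cohort, a
#' yearly-visit cohort, and an external cohort without a year-1 visit.
#' `mean`/`sd` parameterize normal laws (age truncated to 18-75 years),
#' `prob` the Bernoulli indicators; `log2_uacr` is generated normal, so
#' UACR itself is log-normal-like.
#'
#' @return Tibble with columns `country`, `predictor`, `type`, `mean`,
#'   `sd`, `prob`, `lower`, `upper`.
#' @export
default_covariate_table <- function() {
  tribble_row <- function(country, predictor, type, mean = NA, sd = NA, prob = NA,
                          lower = NA, upper = NA) {
    tibble(country = country, predictor = predictor, type = type,
           mean = mean, sd = sd, prob = prob, lower = lower, upper = upper)
  }
  per_country <- list(
    gckd = list(
      age = c(64.0, 8.3), sex = 0.663, smoking_ever = 0.622, bmi = c(32.3, 5.8),
      med_glucose = 0.790, med_bp = 0.981, med_lipid = 0.643,
      map = c(98.5, 12.4), hba1c = c(55.6, 11.2), cholesterol = c(200.1, 45.9),
      hemoglobin = c(13.7, 1.6), log2_uacr = c(5.6, 3.0)
    ),
    provalid = list(
      age = c(62.8, 9.7), sex = 0.517, smoking_ever = 0.505, bmi = c(31.0, 5.3),
      med_glucose = 0.917, med_bp = 0.794, med_lipid = 0.603,
      map = c(99.1, 10.7), hba1c = c(52.8, 12.6), cholesterol = c(186.2, 46.8),
      hemoglobin = c(13.9, 1.5), log2_uacr = c(3.4, 2.5)
    ),
    diacore = list(
      age = c(64.5, 8.3), sex = 0.621, smoking_ever = 0.444, bmi = c(31.0, 5.3),
      med_glucose = 0.868, med_bp = 0.801, med_lipid = 0.487,
      map = c(97.3, 10.8), hba1c = c(51.0, 10.8), cholesterol = c(203.5, 42.4),
      hemoglobin = c(14.4, 1.2), log2_uacr = c(3.6, 1.9)
    )
  )
  rows <- purrr::imap(per_country, function(params, cty) {
    purrr::imap(params, function(val, pred) {
      if (pred %in% egfr_binary_predictors()) {
        tribble_row(cty, pred, "binary", prob = val)
      } else if (pred == "age") {
        # trial eligibility restricts age to 18-75 years
        tribble_row(cty, pred, "truncnorm", mean = val[1], sd = val[2],
                    lower = 18, upper = 75)
      } else {
        tribble_row(cty, pred, "normal", mean = val[1], sd = val[2])
      }
    }) %>% bind_rows()
  }) %>% bind_rows()
  rows
}

#' Default generating fixed effects for the simulator
#'
#' Natural units: eGFR per unit of predictor for main effects, eGFR/yr per
#' unit for the time interactions. Chosen at clinically plausible
#' magnitudes with age dominant; together with the covariate laws the
#' implied mean eGFR slope is about -1.4 mL/min/1.73 m^2 per year.
#'
#' @return Named numeric vector: intercept, 12 mains, `time`, 12
#'   `<predictor>:time` interactions.
#' @export
default_true_effects <- function() {
  c(
    "(Intercept)" = 100,
    age = -0.45, sex = 2, bmi = -0.15, smoking_ever = -1,
    hba1c = -0.05, hemoglobin = 1.0, cholesterol = -0.005, map = -0.05,
    log2_uacr = -1.2, med_glucose = -1, med_bp = -0.5, med_lipid = 0.5,
    time = -0.5,
    "age:time" = -0.005, "sex:time" = 0.05, "bmi:time" = 0,
    "smoking_ever:time" = -0.05, "hba1c:time" = -0.005,
    "hemoglobin:time" = 0, "cholesterol:time" = 0, "map:time" = 0,
    "log2_uacr:time" = -0.08, "med_glucose:time" = 0, "med_bp:time" = 0,
    "med_lipid:time" = 0
  )
}

# mean of a normal truncated to [lower, upper]
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# expected value of each predictor under a covariate-table row
covariate_expectation <- function(row) {
  switch(row$type,
    binary = row$prob,
    normal = row$mean,
    truncnorm = truncnorm_mean(row$mean, row$sd, row$lower, row$upper),
    abort(paste0("unknown covariate type: ", row$type))
  )
}

#' Simulation configuration for a multi-country longitudinal cohort
#'
#' Builds and validates the configuration consumed by [simulate_cohort()].
#' Defaults emulate the three-cohort structure of the development and
#' external-validation populations: a biennial-visit cohort with low
#' baseline eGFR (mean 52.4), a yearly-visit cohort (mean 89.6), and a
#' cohort without a year-1 visit (mean 81.2). When `target_baseline_egfr`
#' is supplied, per-country intercept offsets are solved analytically so
#' the expected baseline eGFR mean equals the target given the covariate
#' generating means; otherwise `offset` is taken from `countries`.
#'
#' @param n_per_country Number of subjects per country (recycled).
#' @param countries Tibble with columns `country`, `schedule` (list-column
#'   of nominal visit times in years, starting at 0) and optionally
#'   `offset` (eGFR units). Defaults to the three-cohort design.
#' @param true_effects Named vector of generating fixed effects: intercept,
#'   the 12 predictor main effects, `time`, and `<predictor>:time`
#'   interactions, in natural units.
#' @param G_true 2x2 covariance of individual (intercept, slope) random
#'   effects; units (eGFR)^2, eGFR*eGFR/yr, (eGFR/yr)^2.
#' @param tau2_true Country-level random intercept variance (eGFR^2).
#' @param sigma2_true Residual measurement variance (eGFR^2).
#' @param covariates Covariate generating-law table (see
#'   `default_covariate_table()` layout: country, predictor, type,
#'   mean, sd, prob, lower, upper).
#' @param target_baseline_egfr Optional named vector of target baseline
#'   eGFR means per country used to solve intercept offsets.
#' @param visit_jitter_sd SD (years) of Gaussian jitter on nominal
#'   follow-up visit times; baseline is never jittered.
#' @param dropout_rate Per-follow-up-visit probability of a missing visit
#'   (missing completely at random).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `egfr_sim_config`.
#' @export
sim_config <- function(n_per_country = 1000,
                       countries = NULL,
                       true_effects = default_true_effects(),
                       G_true = matrix(c(144, -4, -4, 4), 2, 2),
                       tau2_true = 9,
                       sigma2_true = 16,
                       covariates = default_covariate_table(),
                       target_baseline_egfr = c(gckd = 52.4, provalid = 89.6,
                                                diacore = 81.2),
                       visit_jitter_sd = 0.1,
                       dropout_rate = 0.05,
                       seed = 1L) {
  if (is.null(countries)) {
    countries <- tibble(
      country = c("gckd", "provalid", "diacore"),
      schedule = list(c(0, 2, 4), 0:5, c(0, 2, 3, 4, 5))
    )
  }
  if (nrow(countries) == 0) abort("configuration error: empty country list")
  countries$n <- rep_len(as.integer(n_per_country), nrow(countries))
  if (any(countries$n <= 0)) abort("configuration error: n_per_country must be positive")
  bad_schedule <- purrr::map_lgl(countries$schedule, ~ length(.x) == 0 || .x[1] != 0)
  if (any(bad_schedule)) {
    abort("configuration error: every country schedule must start with visit time 0")
  }
  G_true <- as.matrix(G_true)
  if (!isTRUE(all.equal(G_true, t(G_true))) ||
      any(eigen(G_true, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    abort("parameterization error: G_true must be symmetric positive semi-definite")
  }
  if (tau2_true < 0) abort("parameterization error: tau2_true must be >= 0")
  if (sigma2_true < 0) abort("parameterization error: sigma2_true must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("configuration error: dropout_rate must be in [0, 1)")
  }
  if (visit_jitter_sd < 0) abort("configuration error: visit_jitter_sd must be >= 0")

  # countries without covariate laws inherit the first listed archetype
  have_laws <- unique(covariates$country)
  for (cty in setdiff(countries$country, have_laws)) {
    tmpl <- covariates[covariates$country == have_laws[[1]], ]
    tmpl$country <- cty
    covariates <- bind_rows(covariates, tmpl)
  }

  needed <- c("(Intercept)", egfr_predictors(), "time",
              paste0(egfr_predictors(), ":time"))
  missing_fx <- setdiff(needed, names(true_effects))
  if (length(missing_fx) > 0) {
    abort(paste0("configuration error: true_effects missing ",
                 paste(missing_fx, collapse = ", ")))
  }
  true_effects <- true_effects[needed]

  if (!is.null(target_baseline_egfr) && !"offset" %in% names(countries)) {
    countries$offset <- purrr::map_dbl(countries$country, function(cty) {
      if (!cty %in% names(target_baseline_egfr)) return(0)
      tab <- covariates[covariates$country == cty, ]
      mu <- purrr::map_dbl(egfr_predictors(), function(p) {
        covariate_expectation(tab[tab$predictor == p, ])
      })
      target_baseline_egfr[[cty]] -
        (true_effects[["(Intercept)"]] +
           sum(true_effects[egfr_predictors()] * mu))
    })
  }
  if (!"offset" %in% names(countries)) countries$offset <- 0

  structure(
    list(countries = countries, true_effects = true_effects, G_true = G_true,
         tau2_true = tau2_true, sigma2_true = sigma2_true,
         covariates = covariates, visit_jitter_sd = visit_jitter_sd,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "egfr_sim_config"
  )
}

#' @export
print.egfr_sim_config <- function(x, ...) {
  cat("<egfr_sim_config>\n")
  cat("  countries:", paste0(x$countries$country, " (n=", x$countries$n, ")",
                             collapse = ", "), "\n")
  cat("  G_true diag:", diag(x$G_true), " tau2:", x$tau2_true,
      " sigma2:", x$sigma2_true, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

draw_covariate <- function(row, n) {
  switch(row$type,
    binary = rbinom(n, 1, row$prob),
    normal = rnorm(n, row$mean, row$sd),
    truncnorm = {
      # inverse-CDF sampling on the truncated range
      lo <- pnorm(row$lower, row$mean, row$sd)
      hi <- pnorm(row$upper, row$mean, row$sd)
      qnorm(runif(n, lo, hi), row$mean, row$sd)
    },
    abort(paste0("unknown covariate type: ", row$type))
  )
}

#' Generate a synthetic multi-country longitudinal eGFR cohort
#'
#' Draws baseline covariates per country (independently per predictor),
#' realizes country, individual-intercept and individual-slope random
#' effects, and generates noisy eGFR at jittered scheduled visit times:
#' `y = x'beta + offset_c + u_c + b0 + (beta_t + x'gamma + b1) t + eps`.
#' The returned truth table records each subject's realized random effects
#' and true slope for recovery testing; it is never consumed by fitting
#' code.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `egfr_cohort` with elements `baseline` (one row
#'   per subject: id, country, the 12 predictors, `uacr`, `baseline_egfr`),
#'   `visits` (long table: `subject_id`, `country`, `time_since_baseline`,
#'   `egfr`) and `truth` (per-subject realized `b0`, `b1`, country effect
#'   and `true_slope`; plus per-country effects as an attribute).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "egfr_sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  preds <- egfr_predictors()
  fx <- config$true_effects
  gamma <- fx[paste0(preds, ":time")]
  beta_main <- fx[preds]

  # country random deviations on top of the calibrated fixed offsets
  u_country <- rnorm(nrow(config$countries), 0, sqrt(config$tau2_true))
  names(u_country) <- config$countries$country

  Lg <- chol_psd(config$G_true)

  all_base <- list(); all_visits <- list(); all_truth <- list()
  for (k in seq_len(nrow(config$countries))) {
    cty <- config$countries$country[k]
    n <- config$countries$n[k]
    schedule <- config$countries$schedule[[k]]
    ids <- sprintf("%s_%04d", cty, seq_len(n))

    tab <- config$covariates[config$covariates$country == cty, ]
    X <- purrr::map(preds, function(p) {
      row <- tab[tab$predictor == p, ]
      if (nrow(row) != 1) abort(paste0("configuration error: no covariate law for ",
                                       p, " in ", cty))
      draw_covariate(row, n)
    })
    names(X) <- preds
    base <- tibble(subject_id = ids, country = cty, !!!X)
    base$uacr <- 2^base$log2_uacr

    # individual random effects (b0, b1) ~ N(0, G)
    re <- matrix(rnorm(2 * n), n, 2) %*% Lg
    b0 <- re[, 1]; b1 <- re[, 2]

    xb <- as.matrix(base[preds]) %*% beta_main
    level_i <- fx[["(Intercept)"]] + config$countries$offset[k] +
      u_country[[cty]] + drop(xb) + b0
    slope_i <- fx[["time"]] + drop(as.matrix(base[preds]) %*% gamma) + b1

    n_t <- length(schedule)
    tmat <- matrix(rep(schedule, each = n), n, n_t)
    if (config$visit_jitter_sd > 0 && n_t > 1) {
      jit <- matrix(rnorm(n * (n_t - 1), 0, config$visit_jitter_sd), n, n_t - 1)
      tmat[, -1] <- pmax(tmat[, -1] + jit, 0)
    }
    keep <- matrix(TRUE, n, n_t)
    if (config$dropout_rate > 0 && n_t > 1) {
      keep[, -1] <- matrix(runif(n * (n_t - 1)) >= config$dropout_rate, n, n_t - 1)
    }
    eps <- matrix(rnorm(n * n_t, 0, sqrt(config$sigma2_true)), n, n_t)
    ymat <- level_i + slope_i * tmat + eps

    visits <- tibble(
      subject_id = rep(ids, n_t),
      country = cty,
      time_since_baseline = as.vector(tmat),
      egfr = as.vector(ymat),
      .keep_row = as.vector(keep)
    ) %>%
      filter(.data$.keep_row) %>%
      select(-".keep_row") %>%
      arrange(.data$subject_id, .data$time_since_baseline)

    base$baseline_egfr <- ymat[, 1]
    all_base[[k]] <- base
    all_visits[[k]] <- visits
    all_truth[[k]] <- tibble(
      subject_id = ids, country = cty, b0 = b0, b1 = b1,
      country_effect = config$countries$offset[k] + u_country[[cty]],
      true_slope = slope_i
    )
  }

  baseline <- bind_rows(all_base) %>%
    select(all_of(c("subject_id", "country", preds, "uacr", "baseline_egfr")))
  truth <- bind_rows(all_truth)
  attr(truth, "u_country") <- u_country
  structure(
    list(baseline = baseline, visits = bind_rows(all_visits), truth = truth,
         config = config),
    class = "egfr_cohort"
  )
}

#' @export
print.egfr_cohort <- function(x, ...) {
  cat("<egfr_cohort>", nrow(x$baseline), "subjects,",
      nrow(x$visits), "visits,",
      length(unique(x$baseline$country)), "countries\n")
  invisible(x)
}

# upper Cholesky factor that tolerates PSD (zero) matrices
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(vals) * t(e$vectors)))
}

#' Apply the cohort inclusion filters
#'
#' Retains subjects with at least `min_readings` eGFR readings spanning at
#' least `min_span` years and a baseline eGFR of at least
#' `min_baseline_egfr` mL/min/1.73 m^2 (mildly to moderately impaired
#' kidney function). Subjects can fail several criteria at once; the
#' exclusion table counts each criterion separately, so its counts can sum
#' to more than the number of excluded subjects. Idempotent.
#'
#' @param baseline Baseline covariate tibble (one row per subject).
#' @param visits Long visit tibble.
#' @param min_readings Minimum number of eGFR readings (default 3).
#' @param min_span Minimum follow-up span in years (default 2).
#' @param min_baseline_egfr Minimum baseline eGFR (default 30).
#' @return List with filtered `baseline` and `visits`, an `exclusions`
#'   tibble of per-criterion counts, and `n_excluded`.
#' @export
apply_inclusion_filters <- function(baseline, visits, min_readings = 3,
                                    min_span = 2, min_baseline_egfr = 30) {
  stats <- visits %>%
    group_by(.data$subject_id) %>%
    summarise(n_readings = dplyr::n(),
              span = max(.data$time_since_baseline) - min(.data$time_since_baseline),
              .groups = "drop")
  info <- baseline %>% left_join(stats, by = "subject_id")
  info$n_readings[is.na(info$n_readings)] <- 0L
  info$span[is.na(info$span)] <- 0

  fail_readings <- info$n_readings < min_readings
  fail_span <- info$span < min_span
  fail_egfr <- info$baseline_egfr < min_baseline_egfr
  keep <- !(fail_readings | fail_span | fail_egfr)

  exclusions <- tibble(
    reason = c("readings<3", "follow-up<2y", "baseline eGFR<30"),
    n = c(sum(fail_readings), sum(fail_span), sum(fail_egfr))
  )
  exclusions$reason <- c(
    sprintf("readings<%d", min_readings),
    sprintf("follow-up<%gy", min_span),
    sprintf("baseline eGFR<%g", min_baseline_egfr)
  )

  kept_ids <- info$subject_id[keep]
  list(
    baseline = baseline %>% filter(.data$subject_id %in% kept_ids),
    visits = visits %>% filter(.data$subject_id %in% kept_ids),
    exclusions = exclusions,
    n_excluded = sum(!keep)
  )
}

#' CKD-EPI 2021 race-free creatinine eGFR equation
#'
#' Computes eGFR (mL/min/1.73 m^2) from serum creatinine, age and sex with
#' the 2021 refit of the CKD-EPI creatinine equation (no race term):
#' `142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age * 1.012[female]`
#' with k = 0.7 (female) / 0.9 (male) and a = -0.241 / -0.302.
#'
#' @param creatinine Serum creatinine, mg/dL (> 0). Vectorized.
#' @param age Age in years (> 0).
#' @param sex 0 = female, 1 = male (or "female"/"male").
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi_2021 <- function(creatinine, age, sex) {
  if (is.character(sex)) sex <- as.integer(sex == "male")
  if (any(creatinine <= 0) || any(age <= 0)) {
    abort("domain error: creatinine and age must be positive")
  }
  kappa <- ifelse(sex == 1, 0.9, 0.7)
  alpha <- ifelse(sex == 1, -0.302, -0.241)
  ratio <- creatinine / kappa
  142 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.200) *
    0.9938^age * ifelse(sex == 1, 1, 1.012)
}
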