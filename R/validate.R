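#' Predicted R2 for a set of observed/predicted pairs
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`; can be negative
#' for predictions worse than the observed mean. Undefined (NA) with fewer
#' than 2 pairs or zero observed variance.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Scalar, or `NA_real_` when undefined.
#' @export
predicted_r2 <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 2) return(NA_real_)
  ss_tot <- sum((o - mean(o))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((o - p)^2) / ss_tot
}

#' Concordance (C) statistic for a continuous outcome
#'
#' Over all subject pairs with unequal observed values, the fraction whose
#' prediction ordering agrees with the observation ordering; tied
#' predictions receive half credit. Invariant to strictly increasing
#' transforms of the predictions. Undefined (NA) when all observed values
#' are tied.
#'
#' @inheritParams predicted_r2
#' @return Scalar in `[0, 1]`, or `NA_real_` when undefined.
#' @export
c_statistic <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 2) return(NA_real_)
  cnt <- concordance_counts(o, p)
  if (cnt[3] == 0) return(NA_real_)
  (cnt[1] + 0.5 * cnt[2]) / cnt[3]
}

#' Calibration slope for a set of observed/predicted pairs
#'
#' Ordinary least-squares slope of observed on predicted; 1 indicates
#' well-spread predictions, below 1 overdispersed predictions. Undefined
#' (NA) with fewer than 3 pairs or zero prediction variance.
#'
#' @inheritParams predicted_r2
#' @return Scalar, or `NA_real_` when undefined.
#' @export
calibration_slope <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 3) return(NA_real_)
  vp <- var(p)
  if (vp == 0) return(NA_real_)
  cov(p, o) / vp
}

#' Assign follow-up visits to integer year buckets
#'
#' A visit at time `t` (years) belongs to year `y` when
#' `t` is in `(y - 0.5, y + 0.5]`; baseline (`t = 0`) and times outside the
#' requested years are dropped.
#'
#' @param time Numeric vector of times since baseline (years).
#' @param years Integer years to keep (default 1:5).
#' @return Integer vector of the same length; `NA` outside the buckets.
#' @export
year_bucket <- function(time, years = 1:5) {
  y <- as.integer(ceiling(time - 0.5))
  y[!(y %in% years) | time <= 0] <- NA_integer_
  y
}

# per-year metric battery on a pairs table
metrics_by_year <- function(pairs, years = 1:5, predcol = "predicted") {
  purrr::map_dfr(years, function(yy) {
    sub <- pairs[!is.na(pairs$year) & pairs$year == yy, ]
    tibble(
      year = yy, n_pairs = nrow(sub),
      r2 = predicted_r2(sub$observed, sub[[predcol]]),
      c_stat = c_statistic(sub$observed, sub[[predcol]]),
      slope = calibration_slope(sub$observed, sub[[predcol]])
    )
  })
}

# cluster bootstrap over subjects: percentile CIs per year and metric
bootstrap_metrics <- function(pairs, years, n_boot, predcol = "predicted") {
  ids <- unique(pairs$subject_id)
  idx <- split(seq_len(nrow(pairs)), pairs$subject_id)[ids]
  reps <- purrr::map_dfr(seq_len(n_boot), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(idx[take], use.names = FALSE)
    metrics_by_year(pairs[rows, ], years, predcol) %>%
      mutate(.rep = b)
  })
  reps %>%
    group_by(.data$year) %>%
    summarise(
      r2_lo = quantile(.data$r2, 0.025, na.rm = TRUE, names = FALSE),
      r2_hi = quantile(.data$r2, 0.975, na.rm = TRUE, names = FALSE),
      c_lo = quantile(.data$c_stat, 0.025, na.rm = TRUE, names = FALSE),
      c_hi = quantile(.data$c_stat, 0.975, na.rm = TRUE, names = FALSE),
      slope_lo = quantile(.data$slope, 0.025, na.rm = TRUE, names = FALSE),
      slope_hi = quantile(.data$slope, 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

# observed/predicted pairs for all follow-up visits of a cohort under a
# frozen model, with and without baseline-eGFR updating of random effects
prediction_pairs <- function(model, baseline, visits, years = 1:5) {
  post <- posterior_table(model, baseline)
  spec <- model$spec
  design <- build_design(baseline, visits, spec)
  xb <- as.numeric(design$X %*% model$beta)
  key <- as.character(design$subject)
  post_map <- post[match(key, post$subject_id), ]
  pred_no <- xb + post_map$country_effect
  pred_up <- pred_no + post_map$b0 + post_map$b1 * design$time
  tibble(
    subject_id = key,
    country = as.character(design$country),
    time = design$time,
    year = year_bucket(design$time, years),
    observed = design$y,
    predicted = pred_up,
    predicted_noupdate = pred_no
  ) %>% filter(!is.na(.data$year))
}

#' Internal-external (leave-one-country-out) cross-validation
#'
#' For each country, fits the trajectory model on the remaining countries,
#' updates each held-out subject's random effects from their single
#' baseline eGFR, predicts all follow-up visits, pools the held-out
#' observed/predicted pairs across splits, and computes per-follow-up-year
#' predicted R2, C statistic and calibration slope with cluster-bootstrap
#' (subject-level) percentile 95% CIs.
#'
#' @param baseline,visits Cohort tables (already inclusion-filtered).
#' @param spec An [egfr_model_spec()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param years Follow-up years to evaluate (default 1:5).
#' @return An object of class `egfr_validation`: `report` (per-year metrics
#'   and CIs), `pairs` (pooled held-out pairs, with and without updating),
#'   `splits` (per-held-out-country model summaries), `mode = "loco"`.
#' @export
internal_external_cv <- function(baseline, visits, spec = egfr_model_spec(),
                                 n_boot = 1000, seed = NULL, years = 1:5) {
  countries <- sort(unique(baseline$country))
  if (length(countries) < 2) {
    abort("internal-external validation requires at least 2 countries")
  }
  out <- purrr::map(countries, function(cty) {
    tr_b <- baseline %>% filter(.data$country != cty)
    tr_v <- visits %>% filter(.data$subject_id %in% tr_b$subject_id)
    te_b <- baseline %>% filter(.data$country == cty)
    te_v <- visits %>% filter(.data$subject_id %in% te_b$subject_id)
    fit <- fit_egfr_lmm(tr_b, tr_v, spec)
    list(pairs = prediction_pairs(fit, te_b, te_v, years) %>%
           mutate(held_out = cty),
         split = glance(fit) %>% mutate(held_out = cty, .before = 1))
  })
  pairs <- purrr::map_dfr(out, "pairs")
  splits <- purrr::map_dfr(out, "split")
  report <- finalize_report(pairs, years, n_boot, seed)
  structure(list(mode = "loco", report = report, pairs = pairs,
                 splits = splits, n_boot = n_boot, years = years),
            class = "egfr_validation")
}

#' External validation of a frozen trajectory model
#'
#' Applies one fitted model to an external cohort: random effects updated
#' per subject from baseline eGFR (countries unseen in training proceed
#' with a zero country effect and widened variance), follow-up visits
#' predicted, and the same per-year metric battery computed as in
#' [internal_external_cv()].
#'
#' @param model A fitted `egfr_lmm` (possibly loaded via
#'   [read_model_json()]).
#' @param baseline,visits External cohort tables.
#' @inheritParams internal_external_cv
#' @return An `egfr_validation` object with `mode = "external"`.
#' @export
external_validate <- function(model, baseline, visits, n_boot = 1000,
                              seed = NULL, years = 1:5) {
  miss <- setdiff(model$spec$predictors, names(baseline))
  if (length(miss) > 0) {
    abort(paste0("schema error: external baseline table missing model ",
                 "predictor(s): ", paste(miss, collapse = ", ")))
  }
  pairs <- prediction_pairs(model, baseline, visits, years)
  report <- finalize_report(pairs, years, n_boot, seed)
  structure(list(mode = "external", report = report, pairs = pairs,
                 splits = NULL, n_boot = n_boot, years = years),
            class = "egfr_validation")
}

finalize_report <- function(pairs, years, n_boot, seed) {
  point <- metrics_by_year(pairs, years)
  ci <- if (n_boot > 0) {
    if (!is.null(seed)) {
      withr::with_seed(seed, bootstrap_metrics(pairs, years, n_boot))
    } else {
      bootstrap_metrics(pairs, years, n_boot)
    }
  } else {
    tibble(year = years, r2_lo = NA_real_, r2_hi = NA_real_,
           c_lo = NA_real_, c_hi = NA_real_,
           slope_lo = NA_real_, slope_hi = NA_real_)
  }
  point %>%
    left_join(ci, by = "year") %>%
    select(all_of(c("year", "n_pairs", "r2", "r2_lo", "r2_hi",
                    "c_stat", "c_lo", "c_hi",
                    "slope", "slope_lo", "slope_hi")))
}

#' @export
print.egfr_validation <- function(x, ...) {
  cat("<egfr_validation> mode:", x$mode, " pairs:", nrow(x$pairs),
      " bootstrap B:", x$n_boot, "\n")
  print(as.data.frame(x$report), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.egfr_validation <- function(x, ...) {
  x$report %>%
    tidyr::pivot_longer(
      cols = c("r2", "c_stat", "slope"),
      names_to = "metric", values_to = "estimate"
    ) %>%
    mutate(
      conf.low = dplyr::case_when(
        .data$metric == "r2" ~ .data$r2_lo,
        .data$metric == "c_stat" ~ .data$c_lo,
        TRUE ~ .data$slope_lo
      ),
      conf.high = dplyr::case_when(
        .data$metric == "r2" ~ .data$r2_hi,
        .data$metric == "c_stat" ~ .data$c_hi,
        TRUE ~ .data$slope_hi
      )
    ) %>%
    select(all_of(c("year", "n_pairs", "metric", "estimate",
                    "conf.low", "conf.high")))
}
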