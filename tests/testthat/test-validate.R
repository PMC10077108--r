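test_that("metric identities hold for perfect and degenerate predictions", {
  obs <- c(60, 70, 80, 55, 90)
  expect_equal(predicted_r2(obs, obs), 1)
  expect_equal(c_statistic(obs, obs), 1)
  expect_equal(calibration_slope(obs, obs), 1)
  expect_equal(predicted_r2(obs, rep(mean(obs), 5)), 0)
  expect_equal(c_statistic(obs, -obs), 0)
  # undefined cases are NA, not errors
  expect_true(is.na(predicted_r2(c(70, 70), c(60, 65))))
  expect_true(is.na(c_statistic(c(70, 70, 70), c(1, 2, 3))))
  expect_true(is.na(calibration_slope(obs, rep(50, 5))))
})

test_that("hand-computed values on printed triples and constructed lines", {
  # {(60,58),(70,71),(80,77)}: 1 - (4+1+9)/200
  expect_equal(predicted_r2(c(60, 70, 80), c(58, 71, 77)), 1 - 14 / 200)
  # one discordant pair of six comparable
  expect_equal(c_statistic(1:4, c(1, 2, 4, 3)), 5 / 6)
  pred <- c(50, 60, 70, 85)
  expect_equal(calibration_slope(2 * pred - 40, pred), 2)
  expect_equal(calibration_slope(0.9 * pred + 5, pred), 0.9)
})

test_that("C statistic equals brute-force enumeration and survives monotone maps", {
  withr::with_seed(345, {
    for (k in 1:20) {
      n <- sample(5:50, 1)
      obs <- sample(round(rnorm(n, 70, 10)))       # induces ties in obs
      pred <- round(obs + rnorm(n, 0, 8), 1)       # occasional pred ties
      expect_identical(c_statistic(obs, pred), c_statistic_brute(obs, pred))
      # strictly increasing transform leaves concordance unchanged
      expect_equal(c_statistic(obs, exp(pred / 20)),
                   c_statistic(obs, pred), tolerance = 1e-12)
    }
  })
})

test_that("year buckets follow the (y-0.5, y+0.5] convention, baseline excluded", {
  expect_identical(year_bucket(c(0, 0.4, 0.5, 0.51, 1.5, 1.51, 5.5, 5.51)),
                   c(NA, NA, NA, 1L, 1L, 2L, 5L, NA))
})

test_that("leave-one-country-out approaches the perfect-model limit without noise", {
  covs <- default_covariate_table() |> dplyr::filter(country == "provalid")
  covs <- dplyr::bind_rows(dplyr::mutate(covs, country = "a"),
                           dplyr::mutate(covs, country = "b"))
  cfg <- sim_config(
    n_per_country = 100,
    countries = tibble::tibble(country = c("a", "b"),
                               schedule = list(0:4, 0:4)),
    G_true = matrix(0, 2, 2), tau2_true = 0, sigma2_true = 0.01,
    covariates = covs,
    target_baseline_egfr = NULL, visit_jitter_sd = 0.1, dropout_rate = 0,
    seed = 21
  )
  coh <- simulate_cohort(cfg)
  flt <- apply_inclusion_filters(coh$baseline, coh$visits)
  # each training split holds a single country: tau2 is pinned at 0 there
  suppressWarnings(
    cv <- internal_external_cv(flt$baseline, flt$visits, n_boot = 0,
                               years = 1:4)
  )
  expect_true(all(cv$report$r2 > 0.99))
  expect_true(all(abs(cv$report$slope - 1) < 0.02))
  expect_true(all(cv$report$c_stat > 0.98))
})

test_that("metrics are invariant to relabeling and reordering subjects", {
  ch <- shared_cohort()
  cv1 <- internal_external_cv(ch$baseline, ch$visits, n_boot = 0)
  perm <- sample(nrow(ch$baseline))
  b2 <- ch$baseline[perm, ]
  b2$subject_id <- paste0("p_", b2$subject_id)
  v2 <- ch$visits
  v2$subject_id <- paste0("p_", v2$subject_id)
  cv2 <- internal_external_cv(b2, v2, n_boot = 0)
  expect_equal(cv1$report$r2, cv2$report$r2, tolerance = 1e-10)
  expect_equal(cv1$report$c_stat, cv2$report$c_stat, tolerance = 1e-10)
  expect_equal(cv1$report$slope, cv2$report$slope, tolerance = 1e-10)
})

test_that("single-draw bootstrap gives degenerate CIs and fixed seeds reproduce", {
  ch <- shared_cohort()
  cv <- internal_external_cv(ch$baseline, ch$visits, n_boot = 1, seed = 5)
  expect_equal(cv$report$r2_lo, cv$report$r2_hi)
  expect_equal(cv$report$slope_lo, cv$report$slope_hi)
  cv2 <- internal_external_cv(ch$baseline, ch$visits, n_boot = 1, seed = 5)
  expect_equal(cv$report, cv2$report)
})

test_that("external validation reports empty year buckets as missing rows", {
  ch <- shared_cohort()
  fit <- shared_fit()
  # external cohort whose schedule skips year 1 entirely
  cfg <- sim_config(n_per_country = 60,
                    countries = tibble::tibble(country = "newland",
                                               schedule = list(c(0, 2, 3, 4, 5))),
                    target_baseline_egfr = NULL, seed = 71)
  ext <- simulate_cohort(cfg)
  flt <- apply_inclusion_filters(ext$baseline, ext$visits)
  suppressMessages(
    ev <- external_validate(fit, flt$baseline, flt$visits, n_boot = 10, seed = 2)
  )
  y1 <- ev$report[ev$report$year == 1, ]
  expect_equal(y1$n_pairs, 0)
  expect_true(is.na(y1$r2) && is.na(y1$c_stat) && is.na(y1$slope))
  y3 <- ev$report[ev$report$year == 3, ]
  expect_gt(y3$n_pairs, 0)
  expect_false(is.na(y3$r2))
})

test_that("a shifted external country is miscalibrated before updating, restored after", {
  fit <- shared_fit()
  cfg <- sim_config(n_per_country = 80,
                    countries = tibble::tibble(country = "shifted",
                                               schedule = list(0:5)),
                    target_baseline_egfr = NULL, seed = 72)
  ext <- simulate_cohort(cfg)
  ext$baseline$baseline_egfr <- ext$baseline$baseline_egfr + 15
  ext$visits$egfr <- ext$visits$egfr + 15
  flt <- apply_inclusion_filters(ext$baseline, ext$visits)
  suppressMessages(
    ev <- external_validate(fit, flt$baseline, flt$visits, n_boot = 0)
  )
  bias_before <- mean(ev$pairs$observed - ev$pairs$predicted_noupdate)
  bias_after <- mean(ev$pairs$observed - ev$pairs$predicted)
  expect_gt(bias_before, 10)
  # shrinkage makes the restoration partial, but most of the offset goes
  expect_lt(abs(bias_after), 0.5 * abs(bias_before))
})

test_that("schema mismatches against a frozen model fail loudly", {
  fit <- shared_fit()
  ch <- shared_cohort()
  b <- ch$baseline[, setdiff(names(ch$baseline), "hba1c")]
  expect_error(external_validate(fit, b, ch$visits, n_boot = 0),
               "schema error.*hba1c")
})

test_that("calibration plot is built from both prediction sets and backs the visual claim", {
  ch <- shared_cohort()
  cv <- internal_external_cv(ch$baseline, ch$visits, n_boot = 0)
  g <- plot_calibration(cv)
  expect_s3_class(g, "ggplot")
  expect_equal(nrow(g$data), 2 * nrow(cv$pairs))
  # updating tightens agreement with the identity line
  expect_lt(rmse(cv$pairs$observed - cv$pairs$predicted),
            rmse(cv$pairs$observed - cv$pairs$predicted_noupdate))
  # identical prediction sets give identical panels
  cv2 <- cv
  cv2$pairs$predicted_noupdate <- cv2$pairs$predicted
  g2 <- plot_calibration(cv2)
  d2 <- g2$data
  expect_equal(d2$pred[d2$panel == "Before updating"],
               d2$pred[d2$panel == "After updating"])
})
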