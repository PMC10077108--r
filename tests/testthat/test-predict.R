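test_that("posterior update matches joint-Gaussian conditioning on random draws", {
  withr::with_seed(808, {
    for (k in 1:200) {
      A <- matrix(rnorm(4), 2, 2)
      G <- A %*% t(A)
      s2 <- runif(1, 0.05, 10)
      r <- rnorm(1, 0, 5)
      model <- toy_model(G = G, sigma2 = s2)
      post <- update_random_effects(model, toy_subject(baseline_egfr = r))
      oracle <- condition_oracle(G, s2, r)
      expect_lt(max(abs(unname(post$mean) - oracle$mean)), 1e-8)
      expect_lt(max(abs(unname(post$cov) - oracle$cov)), 1e-8)
    }
  })
})

test_that("worked conditioning example: G=[[4,1],[1,.25]], s2=1, r=2 -> (1.6, 0.4)", {
  model <- toy_model(G = matrix(c(4, 1, 1, 0.25), 2, 2), sigma2 = 1)
  post <- update_random_effects(model, toy_subject(baseline_egfr = 2))
  expect_equal(unname(post$mean), c(1.6, 0.4), tolerance = 1e-12)
})

test_that("zero residual leaves effects at prior mean but still shrinks the covariance", {
  G <- matrix(c(9, 1, 1, 2), 2, 2)
  model <- toy_model(G = G, sigma2 = 4)
  post <- update_random_effects(model, toy_subject(baseline_egfr = 0))
  expect_equal(unname(post$mean), c(0, 0))
  dif <- G - post$cov
  expect_true(all(eigen(dif, symmetric = TRUE)$values >= -1e-12))
  expect_true(all(diag(post$cov) <= diag(G)))
})

test_that("an uninformative baseline leaves the prior untouched", {
  G <- matrix(c(9, 1, 1, 2), 2, 2)
  model <- toy_model(G = G, sigma2 = 1e9)
  post <- update_random_effects(model, toy_subject(baseline_egfr = 50))
  expect_lt(max(abs(unname(post$mean))), 1e-6)
  expect_equal(post$cov, G, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("shrinkage never overshoots the residual attribution", {
  withr::with_seed(191, {
    for (k in 1:50) {
      G <- crossprod(matrix(rnorm(4), 2, 2))
      s2 <- runif(1, 0.1, 5)
      r <- rnorm(1, 0, 10)
      model <- toy_model(G = G, sigma2 = s2)
      post <- update_random_effects(model, toy_subject(baseline_egfr = r))
      expect_lte(abs(post$mean[["b0"]]),
                 abs(r) * G[1, 1] / (G[1, 1] + s2) + 1e-12)
    }
  })
})

test_that("noiseless conditioning reproduces the observed baseline exactly", {
  G <- matrix(c(16, -1, -1, 3), 2, 2)
  model <- toy_model(G = G, sigma2 = 0)
  model$beta[["(Intercept)"]] <- 70
  s <- toy_subject(baseline_egfr = 55)
  tr <- predict_trajectory(model, s, times = 0)
  expect_equal(tr$egfr_pred, 55, tolerance = 1e-10)
})

test_that("with zero posterior effects the trajectory is the fixed-effect line", {
  model <- toy_model(G = diag(c(4, 1)), sigma2 = 2)
  model$beta[["(Intercept)"]] <- 80
  model$beta[["time"]] <- -1.3
  post <- structure(list(mean = c(b0 = 0, b1 = 0), cov = diag(c(1, 0.5)),
                         country_effect = 0, country_known = TRUE,
                         residual = 0), class = "egfr_posterior")
  tr <- predict_trajectory(model, toy_subject(80), times = 0:5,
                           posterior = post)
  expect_equal(tr$egfr_pred, 80 - 1.3 * (0:5), tolerance = 1e-12)
})

test_that("slope mean equals the difference quotient of the linear trajectory", {
  fit <- shared_fit()
  s <- fit$baseline[7, ]
  post <- update_random_effects(fit, s)
  sl <- slope_distribution(fit, s, post)
  tr <- predict_trajectory(fit, s, times = c(1, 3.5), posterior = post)
  dq <- (tr$egfr_pred[2] - tr$egfr_pred[1]) / 2.5
  expect_equal(sl$mean, dq, tolerance = 1e-10)
  # all interactions zero and b1 = 0 -> slope is the bare time effect
  model <- toy_model(G = diag(2), sigma2 = 1)
  model$beta[["time"]] <- -2.2
  post0 <- update_random_effects(model, toy_subject(0))
  sl0 <- slope_distribution(model, toy_subject(0), post0)
  expect_equal(sl0$mean, -2.2, tolerance = 1e-12)
})

test_that("posterior slope means track realized true slopes one-for-one", {
  cfg <- exchangeable_config(n_per_country = 334, seed = 606)
  coh <- simulate_cohort(cfg)
  flt <- apply_inclusion_filters(coh$baseline, coh$visits)
  fit <- fit_egfr_lmm(flt$baseline, flt$visits)
  rp <- rapid_progression_table(fit, flt$baseline)
  tru <- coh$truth[match(rp$subject_id, coh$truth$subject_id), ]
  sm <- summary(lm(tru$true_slope ~ rp$slope_mean))$coefficients
  # regression of realized on predicted slopes: unit slope within MC error
  expect_lt(abs(sm[2, 1] - 1), 3 * sm[2, 2])
})

test_that("rapid-progression probability behaves as a normal CDF at the threshold", {
  expect_identical(prob_rapid_progression(-3, sd = 1.7), 0.5)
  expect_equal(prob_rapid_progression(-5, sd = 1), pnorm(2), tolerance = 1e-12)
  # monotone: slower decline, lower risk
  ms <- seq(-6, 2, by = 0.5)
  pr <- prob_rapid_progression(ms, sd = 1.3)
  expect_true(all(diff(pr) < 0))
  # degenerate sd: indicator
  expect_identical(prob_rapid_progression(-4, sd = 0), 1)
  expect_identical(prob_rapid_progression(-2, sd = 0), 0)
  expect_error(prob_rapid_progression(-3, sd = -1), ">= 0")
})

test_that("predictions are invariant to subject order and unrelated duplication", {
  ch <- shared_cohort()
  fit <- shared_fit()
  b <- ch$baseline
  p1 <- egfrtraj:::posterior_table(fit, b)
  shuf <- b[rev(seq_len(nrow(b))), ]
  p2 <- egfrtraj:::posterior_table(fit, shuf)
  p2 <- p2[match(p1$subject_id, p2$subject_id), ]
  expect_equal(p1$b0, p2$b0, tolerance = 1e-12)
  expect_equal(p1$b1, p2$b1, tolerance = 1e-12)
})

test_that("unknown countries get zero effect, widened variance, and a message", {
  fit <- shared_fit()
  s <- fit$baseline[1, ]
  s$country <- "atlantis"
  expect_message(post <- update_random_effects(fit, s), "atlantis")
  expect_false(post$country_known)
  expect_identical(post$country_effect, 0)
  # widened conditioning noise: less shrinkage than for a known country
  s2 <- fit$baseline[1, ]
  post_known <- update_random_effects(fit, s2)
  expect_lt(abs(post$mean[["b0"]] / post$residual),
            abs(post_known$mean[["b0"]] / post_known$residual) + 1e-12)
})

test_that("predictions beyond the 5-year horizon warn and are flagged", {
  fit <- shared_fit()
  s <- fit$baseline[2, ]
  expect_warning(tr <- predict_trajectory(fit, s, times = c(1, 6)),
                 "extrapolation")
  expect_identical(tr$extrapolated, c(FALSE, TRUE))
  expect_error(predict_trajectory(fit, s, times = -1), ">= 0")
})
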