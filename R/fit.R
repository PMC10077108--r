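#' Fit the linear mixed-effects eGFR trajectory model
#'
#' Fits, by restricted (or plain) maximum likelihood, the model
#' \deqn{y_{ij} = x_i'\beta + \beta_t t_{ij} + (x_i t_{ij})'\gamma +
#'   u_{c(i)} + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij}}
#' with country random intercepts \eqn{u_c \sim N(0, \tau^2)}, individual
#' random intercepts and time slopes \eqn{(b_0, b_1) \sim N(0, G)} with
#' unstructured 2x2 covariance, and residuals
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. Baseline eGFR is part of the
#' outcome vector, not a covariate.
#'
#' The implementation profiles \eqn{\beta} and \eqn{\sigma^2} out of the
#' (restricted) log-likelihood and optimizes the profiled criterion over
#' the Cholesky factor of the relative covariance \eqn{G/\sigma^2} plus the
#' relative country standard deviation, using sparse penalized least
#' squares. The Cholesky parameterization enforces positive
#' semi-definiteness; boundary (singular) fits are legal.
#'
#' @param baseline Baseline covariate tibble.
#' @param visits Long visit tibble.
#' @param spec An [egfr_model_spec()]; `spec$method` selects REML/ML.
#' @return An object of class `egfr_lmm`; see [tidy.egfr_lmm()],
#'   [glance.egfr_lmm()], [r2_nakagawa()], [update_random_effects()].
#' @export
fit_egfr_lmm <- function(baseline, visits, spec = egfr_model_spec()) {
  design <- build_design(baseline, visits, spec)
  fit <- lmm_fit_engine(design, method = spec$method)

  kept <- baseline %>% filter(.data$subject_id %in% levels(design$subject))
  cont <- setdiff(spec$predictors, egfr_binary_predictors())
  cont <- cont[cont %in% names(kept)]
  predictor_sds <- purrr::map_dbl(kept[cont], sd)

  structure(
    c(fit,
      list(spec = spec, predictor_sds = predictor_sds,
           baseline = kept,
           visits = visits %>% filter(.data$subject_id %in% kept$subject_id),
           design = design)),
    class = "egfr_lmm"
  )
}

# ---- profiled deviance machinery -------------------------------------------

# Precompute sparse structures reused across deviance evaluations.
lmm_prepare <- function(design) {
  X <- design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("singular-design error: collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  subj <- as.integer(design$subject)
  m <- nlevels(design$subject)
  n <- design$n_obs
  ctry <- as.integer(design$country)
  n_country <- nlevels(design$country)
  use_country <- n_country >= 2
  if (!use_country) {
    warn("single country in training data: country variance fixed at 0")
  }
  q <- 2L * m + if (use_country) n_country else 0L

  # random-effect design Z: per-subject (1, t) then country indicators
  Zi <- c(seq_len(n), seq_len(n), if (use_country) seq_len(n))
  Zj <- c(2L * subj - 1L, 2L * subj, if (use_country) 2L * m + ctry)
  Zx <- c(rep(1, n), design$time, if (use_country) rep(1, n))
  Z <- Matrix::sparseMatrix(i = Zi, j = Zj, x = Zx, dims = c(n, q))

  # relative covariance factor template: theta -> Lambda entries
  Li <- c(2L * seq_len(m) - 1L, 2L * seq_len(m), 2L * seq_len(m),
          if (use_country) 2L * m + seq_len(n_country))
  Lj <- c(2L * seq_len(m) - 1L, 2L * seq_len(m) - 1L, 2L * seq_len(m),
          if (use_country) 2L * m + seq_len(n_country))
  Lind <- c(rep(1L, m), rep(2L, m), rep(3L, m),
            if (use_country) rep(4L, n_country))

  list(X = X, y = design$y, Z = Z, Li = Li, Lj = Lj, Lind = Lind,
       n = n, p = ncol(X), q = q, m = m,
       n_country = n_country, use_country = use_country,
       country_levels = levels(design$country),
       subject_levels = levels(design$subject),
       XtX = crossprod(X), Xty = crossprod(X, design$y))
}

make_lambda <- function(prep, theta) {
  Matrix::sparseMatrix(i = prep$Li, j = prep$Lj, x = theta[prep$Lind],
                       dims = c(prep$q, prep$q))
}

# Penalized least squares at a given theta; returns the profiled criterion
# and, if full = TRUE, all derived quantities at that theta.
lmm_pls <- function(prep, theta, method = "REML", full = FALSE) {
  Lambda <- make_lambda(prep, theta)
  U <- prep$Z %*% Lambda
  UtU <- Matrix::forceSymmetric(Matrix::crossprod(U))
  L <- tryCatch(
    Matrix::Cholesky(UtU, LDL = FALSE, perm = TRUE, Imult = 1),
    error = function(e) NULL
  )
  if (is.null(L)) return(if (full) NULL else 1e10)

  Uty <- Matrix::crossprod(U, prep$y)
  UtX <- Matrix::crossprod(U, prep$X)
  cu <- Matrix::solve(L, Matrix::solve(L, Uty, system = "P"), system = "L")
  RZX <- Matrix::solve(L, Matrix::solve(L, UtX, system = "P"), system = "L")
  RXtRX <- as.matrix(prep$XtX - Matrix::crossprod(RZX))
  Rx <- tryCatch(chol(RXtRX), error = function(e) NULL)
  if (is.null(Rx)) return(if (full) NULL else 1e10)

  rhs <- prep$Xty - as.matrix(Matrix::crossprod(RZX, cu))
  beta <- backsolve(Rx, forwardsolve(t(Rx), rhs))
  u_sph <- Matrix::solve(L, Matrix::solve(L, cu - RZX %*% beta, system = "Lt"),
                         system = "Pt")
  b <- Lambda %*% u_sph
  resid <- prep$y - as.numeric(prep$X %*% beta) - as.numeric(prep$Z %*% b)
  r2 <- sum(resid^2) + sum(u_sph@x^2)

  ldL2 <- 2 * as.numeric(Matrix::determinant(L, sqrt = TRUE)$modulus)
  ldRX2 <- 2 * sum(log(diag(Rx)))
  n <- prep$n; p <- prep$p
  dev <- if (method == "REML") {
    ldL2 + ldRX2 + (n - p) * (1 + log(2 * pi * r2 / (n - p)))
  } else {
    ldL2 + n * (1 + log(2 * pi * r2 / n))
  }
  if (!is.finite(dev)) return(if (full) NULL else 1e10)
  if (!full) return(dev)

  sigma2 <- if (method == "REML") r2 / (n - p) else r2 / n
  list(dev = dev, beta = drop(beta), sigma2 = sigma2,
       beta_cov = sigma2 * chol2inv(Rx), b = as.numeric(b), r2 = r2)
}

lmm_fit_engine <- function(design, method = c("REML", "ML")) {
  method <- match.arg(method)
  prep <- lmm_prepare(design)
  n_theta <- if (prep$use_country) 4L else 3L
  lower <- c(0, -Inf, 0, 0)[seq_len(n_theta)]

  devfun <- function(th) lmm_pls(prep, th, method = method)

  run_opt <- function(start) {
    o1 <- tryCatch(
      optim(start, devfun, method = "L-BFGS-B", lower = lower,
            control = list(factr = 1e3, pgtol = 1e-8, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(o1)) o1 <- list(par = start, value = devfun(start), convergence = 52L)
    # Nelder-Mead polish (theta clamped to bounds inside the wrapper)
    clamp <- function(th) pmax(th, lower)
    o2 <- optim(o1$par, function(th) devfun(clamp(th)),
                method = "Nelder-Mead",
                control = list(reltol = 1e-13, maxit = 2000))
    o2$par <- clamp(o2$par)
    if (o2$value <= o1$value) {
      list(par = o2$par, value = o2$value, convergence = o1$convergence)
    } else o1
  }

  start <- c(1, 0, 1, 0.5)[seq_len(n_theta)]
  opt <- run_opt(start)
  if (opt$convergence != 0 || !is.finite(opt$value)) {
    opt2 <- run_opt(start * 0.5 + 0.25)
    if (is.finite(opt2$value) && opt2$value < opt$value) opt <- opt2
  }
  converged <- is.finite(opt$value) && opt$value < 1e10

  sol <- lmm_pls(prep, opt$par, method = method, full = TRUE)
  theta <- opt$par
  lam <- matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2)
  G <- sol$sigma2 * (lam %*% t(lam))
  tau2 <- if (prep$use_country) sol$sigma2 * theta[4]^2 else 0

  m <- prep$m
  beta <- setNames(sol$beta, colnames(design$X))
  subject_effects <- tibble(
    subject_id = prep$subject_levels,
    b0 = sol$b[2 * seq_len(m) - 1L],
    b1 = sol$b[2 * seq_len(m)]
  )
  country_effects <- if (prep$use_country) {
    setNames(sol$b[2 * m + seq_len(prep$n_country)], prep$country_levels)
  } else {
    setNames(numeric(0), character(0))
  }

  list(
    beta = beta, beta_cov = sol$beta_cov, G = G, tau2 = tau2,
    sigma2 = sol$sigma2, theta = theta,
    loglik = -opt$value / 2, criterion = opt$value, method = method,
    converged = converged,
    country_effects = country_effects,
    subject_effects = subject_effects,
    n_obs = prep$n, n_subjects = prep$m, n_countries = prep$n_country,
    col_names = colnames(design$X)
  )
}

# ---- methods ----------------------------------------------------------------

#' @export
print.egfr_lmm <- function(x, ...) {
  cat("<egfr_lmm> linear mixed-effects eGFR trajectory model (",
      x$method, ")\n", sep = "")
  cat("  ", x$n_obs, " eGFR readings, ", x$n_subjects, " subjects, ",
      x$n_countries, " countries\n", sep = "")
  cat("  sigma2:", format(x$sigma2, digits = 4),
      " tau2:", format(x$tau2, digits = 4), "\n")
  cat("  G: [", format(x$G[1, 1], digits = 4), ",",
      format(x$G[1, 2], digits = 4), ";",
      format(x$G[1, 2], digits = 4), ",",
      format(x$G[2, 2], digits = 4), "]\n")
  cat("  logLik:", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}

#' Tidy the fixed effects of a fitted eGFR trajectory model
#'
#' @param x An `egfr_lmm` fit.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.egfr_lmm <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$beta_cov))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = se,
    conf.low = unname(x$beta) - zc * se,
    conf.high = unname(x$beta) + zc * se
  )
}

#' One-line summary of a fitted eGFR trajectory model
#'
#' @param x An `egfr_lmm` fit.
#' @param ... Unused.
#' @return One-row tibble with sample sizes, variance components,
#'   log-likelihood and marginal/conditional R2.
#' @export
glance.egfr_lmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble(
    nobs = x$n_obs, n_subjects = x$n_subjects, n_countries = x$n_countries,
    sigma2 = x$sigma2, tau2 = x$tau2,
    G_intercept = x$G[1, 1], G_slope = x$G[2, 2], G_cov = x$G[1, 2],
    logLik = x$loglik, method = x$method, converged = x$converged,
    r2_marginal = r2$r2_marginal, r2_conditional = r2$r2_conditional
  )
}
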