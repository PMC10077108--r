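MODEL_SCHEMA_VERSION <- "egfrtraj-model-1"

#' Write a simulated cohort to CSV with a provenance sidecar
#'
#' Writes `baseline.csv` and `visits.csv` (column names as documented in
#' [read_cohort_csv()]) plus `provenance.json` recording the package
#' version, the generating seed, a hash of the simulation configuration
#' and checksums of the written files.
#'
#' @param cohort An `egfr_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  baseline_path <- file.path(dir, "baseline.csv")
  visits_path <- file.path(dir, "visits.csv")
  readr::write_csv(cohort$baseline, baseline_path)
  readr::write_csv(cohort$visits, visits_path)
  prov <- provenance_record(
    seed = cohort$config$seed,
    config = cohort$config,
    files = c(baseline_path, visits_path)
  )
  prov_path <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(baseline = baseline_path, visits = visits_path,
                 provenance = prov_path))
}

provenance_record <- function(seed, config, files = character(0)) {
  cfg <- config
  list(
    package = "egfrtraj",
    version = as.character(utils::packageVersion("egfrtraj")),
    seed = seed,
    config_hash = rlang::hash(cfg),
    input_checksums = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' Read a cohort from baseline and visit CSV files
#'
#' Expected columns: baseline -- `subject_id`, `country`, the 12
#' predictors of [egfr_predictors()] (with `uacr` in mg/g; `log2_uacr` is
#' recomputed if absent) and `baseline_egfr`; visits -- `subject_id`,
#' `country`, `time_since_baseline` (years), `egfr` (mL/min/1.73 m^2).
#' Baseline rows with non-positive UACR are rejected (log2 undefined) with
#' a message, along with their visits; duplicate (subject, time) visit
#' rows are an integrity error.
#'
#' @param baseline_path,visits_path CSV file paths.
#' @return List with `baseline` and `visits` tibbles.
#' @export
read_cohort_csv <- function(baseline_path, visits_path) {
  for (p in c(baseline_path, visits_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  baseline <- readr::read_csv(baseline_path, show_col_types = FALSE,
                              progress = FALSE)
  visits <- readr::read_csv(visits_path, show_col_types = FALSE,
                            progress = FALSE)

  need_base <- c("subject_id", "country",
                 setdiff(egfr_predictors(), "log2_uacr"), "uacr",
                 "baseline_egfr")
  miss <- setdiff(need_base, names(baseline))
  if (length(miss) > 0) {
    abort(paste0("schema error: baseline table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  need_vis <- c("subject_id", "time_since_baseline", "egfr")
  miss_v <- setdiff(need_vis, names(visits))
  if (length(miss_v) > 0) {
    abort(paste0("schema error: visit table missing column(s): ",
                 paste(miss_v, collapse = ", ")))
  }

  bad_uacr <- !is.na(baseline$uacr) & baseline$uacr <= 0
  if (any(bad_uacr)) {
    inform(sprintf("rejected %d baseline row(s) with uacr <= 0 (log2 undefined): rows %s",
                   sum(bad_uacr),
                   paste(utils::head(which(bad_uacr), 10), collapse = ", ")))
    dropped <- baseline$subject_id[bad_uacr]
    baseline <- baseline[!bad_uacr, ]
    visits <- visits %>% filter(!.data$subject_id %in% dropped)
  }
  if (!"log2_uacr" %in% names(baseline)) {
    baseline$log2_uacr <- log2(baseline$uacr)
  }

  dup <- visits %>%
    count(.data$subject_id, .data$time_since_baseline) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("integrity error: duplicate (subject, time) visit rows for ",
                 paste(utils::head(unique(dup$subject_id), 5), collapse = ", ")))
  }
  list(baseline = baseline, visits = visits)
}

#' Persist a fitted trajectory model to versioned JSON
#'
#' Stores everything prediction and external validation need (fixed
#' effects and their covariance, G, tau2, sigma2, country effects,
#' training covariate SDs, column order) so they can run without
#' refitting. Training data are not stored.
#'
#' @param fit An `egfr_lmm`.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(fit, path) {
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    method = fit$method,
    beta = as.list(fit$beta),
    beta_cov = fit$beta_cov,
    G = fit$G,
    tau2 = fit$tau2,
    sigma2 = fit$sigma2,
    theta = fit$theta,
    loglik = fit$loglik,
    converged = fit$converged,
    country_effects = as.list(fit$country_effects),
    predictor_sds = as.list(fit$predictor_sds),
    spec = list(predictors = fit$spec$predictors,
                time_name = fit$spec$time_name,
                interactions = fit$spec$interactions,
                method = fit$spec$method),
    col_names = fit$col_names,
    n_obs = fit$n_obs, n_subjects = fit$n_subjects,
    n_countries = fit$n_countries
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trajectory model persisted with [write_model_json()]
#'
#' @param path JSON path.
#' @return An `egfr_lmm` object (without training data: prediction and
#'   validation work; refitting operations such as
#'   [drop_one_marginal_r2()] do not).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, MODEL_SCHEMA_VERSION)) {
    abort(paste0("model schema mismatch: file has '",
                 obj$schema_version %||% "<none>", "', package expects '",
                 MODEL_SCHEMA_VERSION, "'"))
  }
  spec <- egfr_model_spec(predictors = obj$spec$predictors,
                          time_name = obj$spec$time_name,
                          interactions = obj$spec$interactions,
                          method = obj$spec$method)
  beta <- unlist(obj$beta)
  structure(
    list(beta = beta,
         beta_cov = matrix(unlist(obj$beta_cov), length(beta), length(beta)),
         G = matrix(unlist(obj$G), 2, 2),
         tau2 = obj$tau2, sigma2 = obj$sigma2, theta = obj$theta,
         loglik = obj$loglik, criterion = -2 * obj$loglik,
         method = obj$method, converged = obj$converged,
         country_effects = unlist(obj$country_effects) %||%
           setNames(numeric(0), character(0)),
         predictor_sds = unlist(obj$predictor_sds),
         n_obs = obj$n_obs, n_subjects = obj$n_subjects,
         n_countries = obj$n_countries,
         col_names = obj$col_names, spec = spec),
    class = "egfr_lmm"
  )
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param n_per_country Subjects per country for the simulated cohort.
#' @param n_boot Bootstrap resamples for validation CIs.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param horizon Prediction horizon in years (a value above 5 triggers an
#'   extrapolation warning at prediction time).
#' @param threshold Rapid-progression slope threshold (eGFR/yr).
#' @param fit_method `"REML"` or `"ML"`.
#' @return List of class `egfr_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_per_country = 300, n_boot = 200,
                            seed = 1L, horizon = 5, threshold = -3,
                            fit_method = "REML") {
  structure(
    list(out_dir = out_dir, n_per_country = n_per_country, n_boot = n_boot,
         seed = as.integer(seed), horizon = horizon, threshold = threshold,
         fit_method = fit_method),
    class = "egfr_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the [pipeline_config()] fields;
#'   `out_dir` is required.
#' @return An `egfr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) abort("schema error: pipeline config lacks out_dir")
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' simulate -> write cohort CSVs -> inclusion filters -> fit -> persist
#' model JSON -> leave-one-country-out validation (report JSON +
#' calibration figure) -> demo per-subject prediction table. Every stage
#' writes its artifact under `config$out_dir`; a provenance record ties
#' them to the seed. Deterministic given the configuration.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "egfr_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  sim_cfg <- sim_config(n_per_country = config$n_per_country,
                        seed = config$seed)
  cohort <- simulate_cohort(sim_cfg)
  cohort_paths <- write_cohort_csv(cohort, file.path(config$out_dir, "cohort"))

  flt <- apply_inclusion_filters(cohort$baseline, cohort$visits)

  spec <- egfr_model_spec(method = config$fit_method)
  fit <- fit_egfr_lmm(flt$baseline, flt$visits, spec)
  model_path <- file.path(config$out_dir, "model.json")
  write_model_json(fit, model_path)

  cv <- internal_external_cv(flt$baseline, flt$visits, spec,
                             n_boot = config$n_boot,
                             seed = config$seed + 1L)
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(
    list(seed = config$seed, n_boot = config$n_boot, mode = cv$mode,
         report = cv$report),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  plot_path <- file.path(config$out_dir, "calibration.png")
  plot_ok <- tryCatch({
    g <- plot_calibration(cv)
    ggplot2::ggsave(plot_path, g, width = 9, height = 4.5, dpi = 150)
    TRUE
  }, error = function(e) {
    inform(paste0("calibration figure skipped (no graphics device): ",
                  conditionMessage(e)))
    FALSE
  })

  demo <- flt$baseline[1, ]
  traj <- predict_trajectory(fit, demo, times = 0:config$horizon,
                             horizon = config$horizon)
  slope <- slope_distribution(fit, demo)
  pred_path <- file.path(config$out_dir, "demo_prediction.csv")
  readr::write_csv(
    traj %>% mutate(subject_id = demo$subject_id,
                    slope_mean = slope$mean, slope_sd = slope$sd,
                    prob_rapid = prob_rapid_progression(
                      slope, threshold = config$threshold)),
    pred_path
  )

  prov <- provenance_record(seed = config$seed, config = config,
                            files = c(model_path, report_path, pred_path))
  prov_path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(
    cohort = cohort_paths, model = model_path, report = report_path,
    calibration_plot = if (plot_ok) plot_path else NULL,
    demo_prediction = pred_path, provenance = prov_path,
    fit = fit, validation = cv
  ))
}
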