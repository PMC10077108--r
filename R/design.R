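#' Model specification for the eGFR trajectory model
#'
#' Describes the fixed-effect structure: the baseline predictors, the time
#' variable, which predictors interact with time (all, by default), and the
#' fit criterion. The random structure is fixed by design: individual
#' (intercept, time-slope) with unstructured 2x2 covariance, nested within
#' a country-level random intercept.
#'
#' @param predictors Character vector of baseline predictor column names
#'   (default [egfr_predictors()]).
#' @param time_name Name of the time column in the visit table.
#' @param interactions Either `TRUE` (every predictor interacts with time),
#'   `FALSE` (none), or a character subset of `predictors`.
#' @param method Fit criterion, `"REML"` (default) or `"ML"`.
#' @return An object of class `egfr_model_spec`.
#' @export
egfr_model_spec <- function(predictors = egfr_predictors(),
                            time_name = "time_since_baseline",
                            interactions = TRUE,
                            method = c("REML", "ML")) {
  method <- match.arg(method)
  if (isTRUE(interactions)) {
    interactions <- predictors
  } else if (isFALSE(interactions)) {
    interactions <- character(0)
  } else {
    bad <- setdiff(interactions, predictors)
    if (length(bad) > 0) {
      abort(paste0("unknown interaction predictors: ", paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(predictors = predictors, time_name = time_name,
         interactions = interactions, method = method),
    class = "egfr_model_spec"
  )
}

#' @export
print.egfr_model_spec <- function(x, ...) {
  cat("<egfr_model_spec>", length(x$predictors), "predictors,",
      length(x$interactions), "time interactions, fit:", x$method, "\n")
  invisible(x)
}

# fixed-effect column names in canonical order
design_colnames <- function(spec) {
  c("(Intercept)", spec$predictors, "time",
    if (length(spec$interactions)) paste0(spec$interactions, ":time"))
}

#' Build the fixed-effect design for the eGFR trajectory model
#'
#' Expands the baseline covariates over the visit rows and assembles the
#' fixed-effect matrix `X` with columns: intercept, the baseline predictor
#' main effects, time since baseline, and predictor-by-time products. Row
#' order matches the visit table. Subjects with any missing predictor are
#' dropped (complete-case policy) with an informative message; visits for
#' subjects absent from the baseline table are an error.
#'
#' @param baseline Baseline tibble (one row per subject; must contain
#'   `subject_id`, `country` and every predictor in `spec`).
#' @param visits Long visit tibble (`subject_id`, `time_since_baseline`,
#'   `egfr`).
#' @param spec An [egfr_model_spec()].
#' @return A list of class `egfr_design`: `X` (dense matrix, named
#'   columns), `y`, `time`, `subject` (factor), `country` (factor),
#'   `n_obs`, `n_subjects`, `p`, `n_dropped_incomplete`.
#' @export
build_design <- function(baseline, visits, spec = egfr_model_spec()) {
  req_base <- c("subject_id", "country", spec$predictors)
  miss <- setdiff(req_base, names(baseline))
  if (length(miss) > 0) {
    abort(paste0("schema error: baseline table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  req_vis <- c("subject_id", spec$time_name, "egfr")
  miss_v <- setdiff(req_vis, names(visits))
  if (length(miss_v) > 0) {
    abort(paste0("schema error: visit table missing column(s): ",
                 paste(miss_v, collapse = ", ")))
  }
  unknown <- setdiff(unique(visits$subject_id), baseline$subject_id)
  if (length(unknown) > 0) {
    abort(paste0("integrity error: visits reference subjects absent from the ",
                 "baseline table: ", paste(utils::head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5) ", ..."))
  }

  complete <- stats::complete.cases(baseline[spec$predictors])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    inform(sprintf("complete-case filter: dropped %d of %d subjects with missing predictors",
                   n_dropped, nrow(baseline)))
    baseline <- baseline[complete, ]
    visits <- visits %>% filter(.data$subject_id %in% baseline$subject_id)
  }

  vb <- visits %>%
    select(all_of(c("subject_id", spec$time_name, "egfr"))) %>%
    left_join(baseline[req_base], by = "subject_id")
  tvec <- vb[[spec$time_name]]
  P <- as.matrix(vb[spec$predictors])
  X <- cbind(
    "(Intercept)" = 1,
    P,
    time = tvec,
    if (length(spec$interactions)) {
      XI <- P[, spec$interactions, drop = FALSE] * tvec
      colnames(XI) <- paste0(spec$interactions, ":time")
      XI
    }
  )
  stopifnot(identical(colnames(X), design_colnames(spec)))

  structure(
    list(X = X, y = vb$egfr, time = tvec,
         subject = factor(vb$subject_id, levels = unique(vb$subject_id)),
         country = factor(vb$country),
         n_obs = nrow(X), n_subjects = length(unique(vb$subject_id)),
         p = ncol(X), n_dropped_incomplete = n_dropped,
         spec = spec),
    class = "egfr_design"
  )
}

#' @export
print.egfr_design <- function(x, ...) {
  cat("<egfr_design>", x$n_obs, "rows x", x$p, "fixed-effect columns;",
      x$n_subjects, "subjects,", nlevels(x$country), "countries\n")
  invisible(x)
}
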