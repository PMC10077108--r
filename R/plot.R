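#' Calibration plot: observed vs predicted eGFR by follow-up year
#'
#' Scatter of observed against predicted eGFR for every follow-up visit,
#' before (population prediction) and after empirical-Bayes updating of
#' the random effects with baseline eGFR, side by side. The 45-degree line
#' indicates perfect agreement; later follow-up years are drawn lighter.
#'
#' @param validation An `egfr_validation` object (its `pairs` table
#'   carries both prediction sets).
#' @param years Follow-up years to display.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_calibration <- function(validation, years = validation$years,
                             alpha = 0.4) {
  pairs <- validation$pairs %>% filter(.data$year %in% years)
  long <- bind_rows(
    pairs %>%
      mutate(panel = "Before updating", pred = .data$predicted_noupdate),
    pairs %>%
      mutate(panel = "After updating", pred = .data$predicted)
  ) %>%
    mutate(panel = factor(.data$panel, c("Before updating", "After updating")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pred, y = .data$observed,
                                     colour = .data$year)) +
    ggplot2::geom_abline(intercept = 0, slope = 1) +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::scale_colour_gradient(low = "#08306b", high = "#9ecae1",
                                   name = "Follow-up year") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression("Predicted eGFR (mL/min/1.73" ~ m^2 * ")"),
      y = expression("Observed eGFR (mL/min/1.73" ~ m^2 * ")")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_calibration
#' @param object An `egfr_validation` object.
#' @param ... Passed to [plot_calibration()].
#' @export
autoplot.egfr_validation <- function(object, ...) {
  plot_calibration(object, ...)
}

#' Plot a predicted eGFR trajectory with its predictive band
#'
#' @param trajectory Output of [predict_trajectory()].
#' @param observed Optional tibble of observed visits
#'   (`time_since_baseline`, `egfr`) to overlay.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory, observed = NULL) {
  p <- ggplot2::ggplot(trajectory, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_lo,
                                      ymax = .data$pred_hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$egfr_pred),
                       colour = "steelblue") +
    ggplot2::labs(x = "Years since baseline",
                  y = expression("eGFR (mL/min/1.73" ~ m^2 * ")")) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = observed,
      ggplot2::aes(x = .data$time_since_baseline, y = .data$egfr)
    )
  }
  p
}
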