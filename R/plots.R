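#' Plot binned learning curves
#'
#' @param curves A [binned_learning_curves()] tibble.
#' @return A ggplot: go-rate by bin, one panel per condition.
#' @export
plot_learning_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$bin, y = .data$go_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$partial),
                        show.legend = FALSE) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "trial bin", y = "P(go)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-gonogo
#' @export
autoplot.gng_posterior_predictive <- function(object, ...) {
  curves <- tidyr::pivot_longer(
    object$curves, c("observed_go_rate", "predicted_go_rate"),
    names_to = "source", values_to = "go_rate")
  curves$source <- sub("_go_rate", "", curves$source)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$bin, y = .data$go_rate,
                                       colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "within-condition trial position", y = "P(go)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for fitted objects
#'
#' `gng_model_comparison`: iBIC difference to the best model (lower is
#' better) and mean posterior choice probability per model.
#' `gng_posterior_predictive`: observed vs model-simulated learning
#' curves per condition. `symptom_fit` / `goal_fit`: fixed-effect
#' estimates with 95% Wald intervals.
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-gonogo
NULL

#' @rdname autoplot-gonogo
#' @export
autoplot.gng_model_comparison <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$ibic))
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_ibic, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(Delta * "iBIC (vs best model)"), y = NULL) +
    ggplot2::theme_minimal()
}

coef_forest <- function(coefs, drop_intercept = TRUE) {
  if (drop_intercept) {
    coefs <- dplyr::filter(coefs, .data$term != "(Intercept)")
  }
  coefs$term <- factor(coefs$term, levels = rev(coefs$term))
  ggplot2::ggplot(coefs, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.15) +
    ggplot2::labs(x = "estimate (95% Wald CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-gonogo
#' @export
autoplot.symptom_fit <- function(object, ...) coef_forest(object$coefficients)

#' @rdname autoplot-gonogo
#' @export
autoplot.goal_fit <- function(object, ...) coef_forest(object$coefficients)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
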