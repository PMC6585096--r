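#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate over follow-up days.
#'
#' @param object a `popseg_km`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot popseg_km
#' @export
autoplot.popseg_km <- function(object, ...) {
  d <- bind_rows(tibble(time = 0, survival = 1),
                 select(object$curve, "time", "survival"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days since entry", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot per-segment survival curves
#'
#' @param km_curves stacked curves from [km_by_segment()].
#' @return A ggplot with one step per segment.
#' @export
plot_km_segments <- function(km_curves) {
  starts <- km_curves |>
    distinct(.data$segment) |>
    mutate(time = 0, survival = 1)
  d <- bind_rows(starts,
                 select(km_curves, "segment", "time", "survival"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = .data$segment)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days since entry", y = "Survival probability",
                  colour = "Segment") +
    ggplot2::theme_minimal()
}

#' Forest plot of incidence rate ratios
#'
#' @param object a `popseg_nb` fit.
#' @param ... unused.
#' @return A ggplot of segment IRRs with 95% Wald intervals on a log scale.
#' @method autoplot popseg_nb
#' @export
autoplot.popseg_nb <- function(object, ...) {
  d <- object$irr |> filter(as.character(.data$segment) != "MOSTLY_HEALTHY")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$irr, y = .data$segment)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Incidence rate ratio (vs Mostly Healthy)",
                  y = NULL, title = object$outcome) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
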