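#' @export
autoplot.rig_run <- function(object, ...) {
  meta <- attr(object, "meta")
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                              names_to = "channel", values_to = "temp")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 60,
                                     y = .data$temp,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Elapsed time (min)", y = "Temperature (°C)",
                  colour = NULL,
                  title = sprintf("%s, %.1f m/s, replicate %s",
                                  meta$coverage, meta$velocity,
                                  meta$replicate)) +
    ggplot2::theme_minimal()
}

#' Disturbance and bias versus the surface-to-environment gradient
#'
#' Scatter of the chosen error forms against the gradient with per-group OLS
#' lines, faceted by coverage; air velocity mapped to colour.
#'
#' @param paired Paired steady states from [match_undisturbed()].
#' @param forms Error forms to show.
#' @return A ggplot object.
#' @export
plot_disturbance_bias <- function(paired,
                                  forms = c("disturbance", "bias_from_tu")) {
  long <- paired |>
    tidyr::pivot_longer(c("disturbance", "bias_from_td", "bias_from_tu"),
                        names_to = "form", values_to = "value") |>
    dplyr::filter(.data$form %in% forms,
                  !(.data$form != "disturbance" & is.na(.data$t_sen)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gradient, y = .data$value,
                                     colour = factor(.data$velocity),
                                     shape = .data$form)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~coverage) +
    ggplot2::labs(x = "Surface-to-environment gradient (°C)",
                  y = "Error (°C)", colour = "Air velocity (m/s)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Inter-sensor mean differences by period and source
#'
#' Mean differences with 95% CI error bars per summary period, comparing the
#' model-derived values at each air velocity with the human trial, faceted by
#' sensor pair.
#'
#' @param comparison Output of [compare_with_trial()] (or any tibble with
#'   `pair`, `period`, `source`, `mean`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_intersensor_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$period, y = .data$mean,
                               colour = .data$source)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~pair, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Mean difference (°C)", colour = NULL) +
    ggplot2::theme_minimal()
}
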