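# ggplot2 views of the main result types

#' Plot a gated cytogram
#'
#' Green fluorescence against side scatter on log axes, coloured by gate
#' label, with the fluorescence threshold drawn when present.
#'
#' @param object Gated events from [gate_populations()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_gated <- function(object, ...) {
  gate <- attr(object, "gate")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$ssc_raw, y = .data$gf_raw,
                                    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "side scatter (raw)", y = "green fluorescence (raw)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(gate) && is.finite(gate$threshold_gf)) {
    p <- p + ggplot2::geom_hline(yintercept = gate$threshold_gf,
                                 linetype = "dashed")
  }
  p
}

#' Monthly temperature-response slopes with confidence intervals
#'
#' Point-range plot of the monthly OLS slopes per group, faceted by response
#' and treatment; open symbols mark slopes whose 95% CI includes zero.
#'
#' @param slopes Output of [temperature_slopes()].
#' @return A ggplot.
#' @export
plot_temperature_slopes <- function(slopes) {
  ggplot2::ggplot(slopes,
                  ggplot2::aes(x = .data$month, y = .data$slope,
                               colour = .data$group,
                               shape = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_grid(response ~ treatment, scales = "free_y") +
    ggplot2::labs(y = "slope per degC", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Arrhenius plot of a fitted activation energy
#'
#' @param object An `mt_arrhenius` fit.
#' @param ... Unused.
#' @return A ggplot of ln(rate) against 1/kT with the fitted line.
#' @export
autoplot.mt_arrhenius <- function(object, ...) {
  fit <- attr(object, "fit")
  df <- tibble::tibble(x = fit$model$x, y = fit$model$`log(rates)`)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "1 / kT (eV^-1)", y = "ln growth rate",
                  subtitle = paste0("E = ", signif(object$e_ev, 3), " eV")) +
    ggplot2::theme_minimal()
}
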