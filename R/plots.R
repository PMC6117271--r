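#' Plot a correlation curve
#'
#' @param object A `correlation_curve` from [temporal_autocorrelation()] or
#'   [spatial_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlation_curve
#' @export
autoplot.correlation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag", y = "correlation") +
    ggplot2::theme_minimal()
}

#' Plot a fitted vexation and frustration
#'
#' Two panels: the per-bin vexation profile and the frustration versus
#' occupancy, each with 1-sd error bars from the Fisher covariance.
#'
#' @param object A `dfft_fit`.
#' @param ... Unused.
#' @return A ggplot (facetted).
#' @method autoplot dfft_fit
#' @export
autoplot.dfft_fit <- function(object, ...) {
  td <- tidy(object)
  td$kind <- ifelse(grepl("^f_", td$term), "frustration f_N", "vexation v_b")
  td$index <- as.numeric(sub("^[fv]_", "", td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$index, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std.error,
      ymax = .data$estimate + .data$std.error
    ), size = 0.2) +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "bin b / occupancy N", y = "dissatisfaction") +
    ggplot2::theme_minimal()
}

#' Plot pseudo-free energies per bin
#'
#' Curvature away from a straight line signals interactions: upward
#' bending means repulsion, downward attraction.
#'
#' @param hist An `occupancy_histograms` tibble.
#' @param bins Bins to display (default: all).
#' @return A ggplot.
#' @export
plot_pseudo_free_energy <- function(hist, bins = NULL) {
  pfe <- pseudo_free_energy(hist)
  if (!is.null(bins)) pfe <- pfe[pfe$bin %in% bins, ]
  ggplot2::ggplot(pfe, ggplot2::aes(
    x = .data$n, y = .data$value,
    group = .data$bin, colour = factor(.data$bin)
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$value - .data$sd,
      ymax = .data$value + .data$sd
    ), size = 0.2) +
    ggplot2::labs(
      x = "occupancy N", y = expression(-ln(N ~ "!" ~ P[b](N))),
      colour = "bin"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the frustration collapse
#'
#' Pseudo-free energies with the per-bin Poisson part removed, overlaid on
#' the fitted frustration. A tight collapse supports a single universal
#' \eqn{f_N}.
#'
#' @param object A `collapse_table` from [collapse_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot collapse_table
#' @export
autoplot.collapse_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f), colour = "black") +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        y = .data$collapsed, ymin = .data$collapsed - .data$sd,
        ymax = .data$collapsed + .data$sd, colour = factor(.data$bin)
      ),
      size = 0.2, alpha = 0.7
    ) +
    ggplot2::labs(x = "occupancy N", y = expression(f[N]), colour = "bin") +
    ggplot2::theme_minimal()
}

#' Plot predicted against observed mean occupations
#'
#' @param object A `comparison_report` from [compare_distributions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed mean occupation", y = "predicted mean occupation") +
    ggplot2::theme_minimal()
}
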