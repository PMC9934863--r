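#' Plot Sholl profiles
#'
#' @param profiles a tibble of [sholl()] outputs, optionally with a grouping
#'   column (e.g. `cell_type`).
#' @param colour optional name of a grouping column.
#' @return A ggplot.
#' @export
plot_sholl <- function(profiles, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(.data$radius_um, .data$n_intersections)
  } else {
    ggplot2::aes(.data$radius_um, .data$n_intersections,
                 colour = .data[[colour]], group = .data[[colour]])
  }
  ggplot2::ggplot(profiles, aes) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "Distance from soma (µm)",
                  y = "Intersections") +
    ggplot2::theme_minimal()
}

#' Soma vs dendritic bipolarity scatter
#'
#' @param features tibble with `soma_bipolarity`, `dendritic_bipolarity`,
#'   and a `cell_type` column.
#' @return A ggplot.
#' @export
plot_bipolarity <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(.data$soma_bipolarity,
                               .data$dendritic_bipolarity,
                               colour = .data$cell_type)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Soma bipolarity (major/minor axis)",
                  y = "Dendritic bipolarity (fraction near poles)",
                  colour = "Type") +
    ggplot2::theme_minimal()
}

#' Coupling symmetry: one direction against the other
#'
#' @param estimates tibble of coupled-pair estimates (`cc_ij`, `cc_ji`).
#' @return A ggplot with the identity line and the fitted regression.
#' @export
plot_coupling_symmetry <- function(estimates) {
  ggplot2::ggplot(estimates, ggplot2::aes(.data$cc_ij, .data$cc_ji)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Coupling coefficient (direction 1)",
                  y = "Coupling coefficient (direction 2)") +
    ggplot2::theme_minimal()
}

#' Connectivity rate by distance bin
#'
#' @param rates output of [connectivity_rates()] with a `distance_bin`
#'   column.
#' @return A ggplot.
#' @export
plot_connectivity_rates <- function(rates) {
  ggplot2::ggplot(dplyr::filter(rates, !is.na(.data$rate)),
                  ggplot2::aes(.data$distance_bin, .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Inter-soma distance (µm)",
                  y = "Connection rate") +
    ggplot2::theme_minimal()
}

#' Observed motif counts against Monte Carlo prediction intervals
#'
#' @param object a `motif_prediction`.
#' @param ... unused.
#' @return A ggplot showing, per motif category, the Monte Carlo mean and
#'   95% interval with the observed count overlaid.
#' @method autoplot motif_prediction
#' @export
autoplot.motif_prediction <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$motif)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mc_mean,
                                          ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "firebrick", size = 3, shape = 18) +
    ggplot2::labs(x = NULL, y = "Count",
                  title = "Observed (diamonds) vs model prediction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
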