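#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_errorbarh
#'   geom_vline geom_line labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Forest plot of standardized coefficients
#'
#' Posterior means with 95% credible intervals; open circles mark
#' coefficients whose interval includes zero ("no association").
#'
#' @param object A [fit_glmm()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gs_glmm <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot(d, aes(x = .data$estimate,
                y = stats::reorder(.data$term, .data$estimate))) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.2) +
    geom_point(aes(shape = .data$no_association), size = 2.4) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    labs(x = "posterior mean (95% credible interval)", y = NULL) +
    theme_minimal()
}

#' Map a per-cell value over the lattice
#'
#' @param grid A [make_grid()] lattice.
#' @param values Tibble `cell_id`, value column.
#' @param value Name of the value column.
#' @return A ggplot tile map.
#' @export
plot_cell_map <- function(grid, values, value) {
  d <- dplyr::left_join(tibble::as_tibble(grid), values, by = "cell_id")
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data[[value]])) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = value) +
    theme_minimal()
}

#' Stepwise R-squared trajectory plot
#'
#' @param object A [stepwise_r2()] table.
#' @param ... Unused.
#' @return A ggplot of marginal and conditional R-squared by step.
#' @export
autoplot.gs_stepwise <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("r2_marginal", "r2_conditional"),
                           names_to = "which", values_to = "r2")
  ggplot(d, aes(x = .data$step, y = .data$r2, colour = .data$which)) +
    geom_line() + geom_point() +
    ggplot2::scale_x_continuous(breaks = object$step, labels = object$group) +
    labs(x = NULL, y = expression(R^2), colour = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
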