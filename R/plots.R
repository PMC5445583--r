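#' Plot an occupancy state
#'
#' Tile map of the lattice; occupied sites are filled.
#'
#' @param object An [occupancy_state()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_state <- function(object, ...) {
  df <- object$agents
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(fill = "#2c7fb8") +
    ggplot2::coord_fixed(xlim = c(0.5, object$domain$Lx + 0.5),
                         ylim = c(0.5, object$domain$Ly + 0.5),
                         expand = FALSE) +
    ggplot2::labs(x = "column i", y = "row j") +
    ggplot2::theme_minimal()
}

#' Plot the ensemble summary statistics of a dataset
#'
#' One panel per statistic and sampling time; density profiles against
#' column index, PCF against pair separation.
#'
#' @param object A `summary_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.summary_dataset <- function(object, ...) {
  df <- filter(object$ensemble, .data$statistic != "displacement")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$value,
                                   colour = factor(.data$t))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$statistic, scales = "free") +
    ggplot2::labs(x = "element (column i / separation m)", y = "value",
                  colour = "t (min)") +
    ggplot2::theme_minimal()
}

#' Plot a discretised posterior
#'
#' Heat map of the probability mass over the prior box.
#'
#' @param object A `grid_posterior`.
#' @param truth Optional `c(pm, alpha)` marked with a point.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_posterior <- function(object, truth = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pm, y = .data$alpha,
                                        fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(P[m]), y = expression(alpha),
                  fill = "mass") +
    ggplot2::theme_minimal()
  if (!is.null(truth))
    p <- p + ggplot2::annotate("point", x = truth[1], y = truth[2],
                               colour = "red", size = 2)
  p
}

#' @rdname autoplot.grid_posterior
#' @param object An `abc_posterior`; it is discretised first.
#' @param n_bins Bins per parameter.
#' @export
autoplot.abc_posterior <- function(object, truth = NULL, n_bins = 64, ...) {
  autoplot(discretize_posterior(object, n_bins = n_bins), truth = truth)
}
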