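#' Heatmap of an F_u grid
#'
#' Distance bins on the horizontal axis, neighborhood radii on the
#' vertical axis, cell fill giving the mean fraction of unique
#' functions; empty cells are blank.  The dashed line marks r = d/2,
#' below which the two balls cannot overlap.
#'
#' @param grid An `fu_grid` from [aggregate_grid()] (or an
#'   `fu_grid_summary`).
#' @return A ggplot object.
#' @export
plot_fu_heatmap <- function(grid) {
  g <- as_tibble(grid)
  g$d_mid <- (g$d_bin_lo + g$d_bin_hi) / 2
  ggplot2::ggplot(g[!is.na(g$mean_fu), ],
                  ggplot2::aes(x = d_mid, y = r, fill = mean_fu)) +
    ggplot2::geom_tile() +
    ggplot2::geom_abline(slope = 0.5, intercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_viridis_c(name = expression(bar(F)[u]),
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "sequence distance d (%)",
                  y = "neighborhood radius r (%)") +
    ggplot2::theme_minimal()
}

#' F_u versus distance at constant radii
#'
#' One curve per neighborhood radius: mean F_u across distance bins
#' with standard-error bars, the flattened view of the grid heatmap.
#'
#' @param grid An `fu_grid`.
#' @return A ggplot object.
#' @export
plot_fu_curves <- function(grid) {
  g <- as_tibble(grid)
  g <- g[!is.na(g$mean_fu), ]
  g$d_mid <- (g$d_bin_lo + g$d_bin_hi) / 2
  se_lo <- pmax(g$mean_fu - g$se, 0)
  se_hi <- pmin(g$mean_fu + g$se, 1)
  ggplot2::ggplot(g, ggplot2::aes(x = d_mid, y = mean_fu,
                                  colour = factor(r), group = factor(r))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = se_lo, ymax = se_hi),
                           width = 1, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_d(name = "radius r (%)") +
    ggplot2::labs(x = "sequence distance d (%)",
                  y = "fraction of unique functions") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname plot_fu_curves
#' @param object An `fu_grid`.
#' @param ... Unused.
#' @export
autoplot.fu_grid <- function(object, ...) plot_fu_curves(object)

#' Histogram of structural promiscuity values
#'
#' @param object A `promiscuity_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.promiscuity_tbl <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = R_F)) +
    ggplot2::geom_histogram(binwidth = 0.02, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = expression(R[F]), y = "number of functions") +
    ggplot2::theme_minimal()
}

#' Histogram of functional versatility values
#'
#' @param object A `versatility_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.versatility_tbl <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = V_S)) +
    ggplot2::geom_histogram(binwidth = 0.02, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = expression(V[S]), y = "number of structures") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
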