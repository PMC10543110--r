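# ggplot2 helpers for the main result types.

#' Plot an unfolded map
#'
#' Raster view of a per-vertex map in unfolded coordinates (AP along rows,
#' PD along columns).
#'
#' @param map an [unfolded_map()].
#' @param title optional title (defaults to the metric name).
#' @return a ggplot object.
#' @export
plot_unfolded <- function(map, title = NULL) {
  gs <- map$grid_shape
  df <- data.frame(row = rep(seq_len(gs[1]), gs[2]),
                   col = rep(seq_len(gs[2]), each = gs[1]),
                   value = map$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title %||% map$metric,
                  x = "anterior-posterior", y = "proximal-distal",
                  fill = map$metric) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a split-half stability report
#'
#' Stability coefficient (mean +/- 1 SD) and reconstruction-error gradient
#' as a function of the number of components.
#'
#' @param report a [stability_analysis()] result.
#' @return a ggplot object.
#' @export
plot_stability <- function(report) {
  df <- as.data.frame(report)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$stability_mean - .data$stability_sd,
      ymax = .data$stability_mean + .data$stability_sd), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$stability_mean), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$stability_mean), colour = "steelblue") +
    ggplot2::labs(x = "number of components k", y = "stability coefficient") +
    ggplot2::theme_minimal()
}

#' Plot a winner-take-all parcellation
#'
#' @param fit an [opnnmf_fit()] result.
#' @param grid_shape (rows, cols) of the unfolded grid.
#' @return a ggplot object.
#' @export
plot_parcellation <- function(fit, grid_shape) {
  m <- unfolded_map(fit$labels, grid_shape, metric = "component")
  gs <- m$grid_shape
  df <- data.frame(row = rep(seq_len(gs[1]), gs[2]),
                   col = rep(seq_len(gs[2]), each = gs[1]),
                   component = factor(m$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$component)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "anterior-posterior", y = "proximal-distal") +
    ggplot2::theme_minimal()
}
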