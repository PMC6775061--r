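## ggplot2 views of the main result types.

#' @export
autoplot.landscape_model <- function(object, spacing = 0.1, ...) {
  g <- landscape_grid(spacing, xlim = c(0, 15), ylim = c(0, 7))
  df <- tibble::tibble(lock = g$X[, 1], rmsd = g$X[, 2],
                       U = landscape_potential(object, g$X[, 1], g$X[, 2]))
  df$U <- pmin(df$U - min(df$U), 8)
  ggplot2::ggplot(df, ggplot2::aes(.data$lock, .data$rmsd)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$U)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$U), colour = "white",
                          linewidth = 0.2, bins = 12) +
    ggplot2::geom_text(data = object$basins,
                       ggplot2::aes(.data$lock, .data$rmsd,
                                    label = .data$state),
                       colour = "red", size = 3) +
    ggplot2::scale_fill_viridis_c(name = "U (kcal/mol)",
                                  direction = -1) +
    ggplot2::labs(x = "R3.50-E6.30 distance (Å)",
                  y = "Y7.53 RMSD from inactive (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.population_estimate <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$state, 100 * .data$population)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$population - .data$sd),
      ymax = 100 * (.data$population + .data$sd)), width = 0.25) +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$target),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "population (%)",
                  caption = "crosses: generator targets") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msm_model <- function(object, n = 8, ...) {
  its <- implied_timescales(object, n = n)
  its <- its[is.finite(its$timescale), ]
  ggplot2::ggplot(its, ggplot2::aes(factor(.data$index),
                                    .data$timescale)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "process", y = "implied timescale (frames)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flux_network <- function(object, threshold = 0.01, ...) {
  Fm <- object$F
  n <- nrow(Fm)
  idx <- which(Fm > threshold * object$total_flux, arr.ind = TRUE)
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  nodes <- tibble::tibble(state = object$labels,
                          x = cos(ang), y = sin(ang),
                          pi = object$pi)
  edges <- tibble::tibble(
    x = nodes$x[idx[, 1]], y = nodes$y[idx[, 1]],
    xend = nodes$x[idx[, 2]], yend = nodes$y[idx[, 2]],
    flux = Fm[idx])
  ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(xend = .data$xend, yend = .data$yend,
                   linewidth = .data$flux),
      arrow = ggplot2::arrow(length = ggplot2::unit(8, "pt")),
      colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$pi),
                        colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), vjust = -1.4) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::scale_size(range = c(2, 8), guide = "none") +
    ggplot2::theme_void()
}

#' 2D density histogram of feature trajectories
#'
#' The synthetic analogue of the activation-landscape density map: a
#' hexagonally binned histogram of the frames over the two descriptors.
#'
#' @param features Tibble with `lock_distance` and `y753_rmsd`.
#' @param bins Number of hexagonal bins per axis.
#' @return A ggplot object.
#' @export
plot_landscape_density <- function(features, bins = 80) {
  ggplot2::ggplot(features, ggplot2::aes(.data$lock_distance,
                                         .data$y753_rmsd)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_fill_viridis_c(trans = "log10", name = "frames") +
    ggplot2::labs(x = "R3.50-E6.30 distance (Å)",
                  y = "Y7.53 RMSD from inactive (Å)") +
    ggplot2::theme_minimal()
}
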