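#' Plot the maze layout
#'
#' Draws the 14 sectors and, optionally, the four route centerlines.
#'
#' @param layout A [build_maze_layout()] object.
#' @param routes Draw centerlines? Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_maze <- function(layout, routes = TRUE) {
  polys <- purrr::imap_dfr(layout$sectors, function(p, nm)
    tibble::tibble(sector = nm, x = p[, 1], y = p[, 2]))
  g <- ggplot2::ggplot(polys, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$sector),
                          fill = "grey92", colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
  if (routes) {
    cl <- purrr::imap_dfr(layout$routes, function(r, i)
      tibble::tibble(route = factor(i), x = r$centerline[, 1],
                     y = r$centerline[, 2]))
    g <- g + ggplot2::geom_path(data = cl,
                                ggplot2::aes(colour = .data$route),
                                linewidth = 0.8)
  }
  g
}

#' @rdname autoplot-routecells
#' @export
autoplot.rate_map <- function(object, ...) {
  df <- tidyr::expand_grid(yi = seq_along(object$y_centres),
                           xi = seq_along(object$x_centres))
  df$x <- object$x_centres[df$xi]
  df$y <- object$y_centres[df$yi]
  df$rate <- as.vector(object$rate[cbind(df$xi, df$yi)])
  ggplot2::ggplot(df[!is.na(df$rate), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Hz") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for analysis results
#'
#' `autoplot.rate_map` renders the firing rate map; `autoplot.decoding_result`
#' tiles the route-by-goal match percentages (annotated with shuffle
#' p-values when available).
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-routecells
#' @export
autoplot.decoding_result <- function(object, ...) {
  d <- tidy(object)
  g <- ggplot2::ggplot(d, ggplot2::aes(.data$goal, .data$route,
                                       fill = .data$match_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% matched", limits = c(0, 100)) +
    ggplot2::theme_minimal()
  if (!is.null(d$p_value)) {
    g <- g + ggplot2::geom_text(
      ggplot2::aes(label = sprintf("p=%.3g", .data$p_value)),
      colour = "white", size = 3)
  }
  g
}

#' Plot the sector activity profile
#'
#' Active-cell counts against sector distance rank from the start box.
#'
#' @param profile Result of [sector_activity_profile()].
#' @return A ggplot object.
#' @export
plot_sector_profile <- function(profile) {
  d <- profile$profile
  ggplot2::ggplot(d, ggplot2::aes(.data$distance_rank, .data$active_cells)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(x = "distance rank from start box",
                  y = "active place cells") +
    ggplot2::theme_minimal()
}
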