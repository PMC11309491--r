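#' Plot a population state
#'
#' Draws every cell as an ellipse coloured by its nematic orientation
#' (hue of `2 * alpha`, so `alpha` and `alpha + pi` share a colour) with
#' an orientation arrow, in the periodic box.
#'
#' @param cells A [cell_population()] tibble.
#' @param box_l Box side length (axis limits).
#' @param junctions Optional [find_junctions()] tibble drawn as grey
#'   segments.
#' @param n_vertices Polygon resolution per ellipse.
#' @return A ggplot object.
#' @export
plot_population <- function(cells, box_l, junctions = NULL,
                            n_vertices = 40L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)
  poly <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    bp <- boundary_point(cells[i, , drop = FALSE], theta = theta)
    tibble::tibble(cell = cells$cell[i], px = bp$px, py = bp$py,
                   hue = wrap_angle(2 * cells$alpha[i]))
  })
  arrows <- dplyr::mutate(
    cells,
    xend = .data$x + 0.8 * sqrt(.data$r) * cos(.data$alpha),
    yend = .data$y + 0.8 * sqrt(.data$r) * sin(.data$alpha)
  )
  p <- ggplot2::ggplot()
  if (!is.null(junctions) && nrow(junctions)) {
    ep <- cell_endpoints(cells)
    seg <- dplyr::mutate(
      junctions,
      x0 = ifelse(.data$end_i == "front", ep$front_x[.data$i],
                  ep$back_x[.data$i]),
      y0 = ifelse(.data$end_i == "front", ep$front_y[.data$i],
                  ep$back_y[.data$i])
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x0 + .data$sep_x,
                   yend = .data$y0 + .data$sep_y),
      colour = "grey40", linewidth = 1
    )
  }
  p +
    ggplot2::geom_polygon(
      data = poly,
      ggplot2::aes(.data$px, .data$py, group = .data$cell,
                   fill = .data$hue),
      colour = "grey20", linewidth = 0.2, alpha = 0.85
    ) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")),
      linewidth = 0.3
    ) +
    ggplot2::scale_fill_gradientn(
      colours = c("#d73027", "#fee090", "#1a9850", "#4575b4", "#d73027"),
      limits = c(0, 2 * pi), guide = "none"
    ) +
    ggplot2::coord_fixed(xlim = c(0, box_l), ylim = c(0, box_l),
                         expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_population
#' @param object A `cell_traj` object.
#' @param t Frame time (or `"last"`/`"first"`).
#' @param ... Unused.
#' @export
autoplot.cell_traj <- function(object, t = "last", ...) {
  cells <- get_frame(object, t)
  jn <- get_junctions(object, t)
  plot_population(cells, object$params$box_l,
                  junctions = if (nrow(jn)) {
                    find_junctions(cells, object$params$lam,
                                   object$params$box_l)
                  }) +
    ggplot2::ggtitle(sprintf("t = %g, alignment = %.2f", attr(cells, "t"),
                             nematic_alignment(cells)))
}

#' @rdname run_sweep
#' @param object A `cell_sweep` object.
#' @export
autoplot.cell_sweep <- function(object, ...) {
  s <- tidy(object)
  ggplot2::ggplot(s, ggplot2::aes(.data$value, .data$mean_alignment)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_alignment - .data$sd_alignment,
                   ymax = .data$mean_alignment + .data$sd_alignment),
      width = 0
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$spec$param, y = "equilibrated alignment") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Alignment time series plot
#'
#' @param traj A `cell_traj` object.
#' @return A ggplot object.
#' @export
plot_alignment <- function(traj) {
  ggplot2::ggplot(alignment_series(traj),
                  ggplot2::aes(.data$t, .data$alignment)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "t", y = "alignment") +
    ggplot2::theme_minimal()
}
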