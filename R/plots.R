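# ggplot2 views of the core result types.

#' @method autoplot forest_map
#' @export
autoplot.forest_map <- function(object, ...) {
  v <- object$values
  px <- object$pixel_size
  d <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  d$x <- object$origin[1] + (d$col - 0.5) * px
  d$y <- object$origin[2] - (d$row - 0.5) * px
  d$class <- factor(ifelse(is.na(as.vector(t(v))), "nodata",
                           ifelse(as.vector(t(v)) == 1, "forest", "non-forest")),
                    levels = c("forest", "non-forest", "nodata"))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(forest = "#1b7837",
                                          `non-forest` = "#f7f7f7",
                                          nodata = "grey70"),
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Forest map, epoch %s", format(object$epoch))) +
    ggplot2::theme_minimal()
}

#' Map a per-cell layer over the analysis grid
#'
#' @param layers An [ffi_layers()] or [classify_changes()] table.
#' @param grid The matching [build_grid()] grid.
#' @param var Column of `layers` to map (default `"d_ffi"`).
#' @return A ggplot object.
#' @export
plot_cell_layer <- function(layers, grid, var = "d_ffi") {
  d <- dplyr::inner_join(
    dplyr::select(grid, "cell_id", "x_center", "y_center"),
    layers, by = "cell_id")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_center, .data$y_center)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = var) +
    ggplot2::theme_minimal()
  if (is.numeric(d[[var]])) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data[[var]]))
    if (grepl("^d_", var)) {
      p <- p + ggplot2::scale_fill_gradient2(low = "#1a9850", mid = "#ffffbf",
                                             high = "#d73027", midpoint = 0)
    } else {
      p <- p + ggplot2::scale_fill_viridis_c()
    }
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data[[var]]))
  }
  p
}

#' @method autoplot ffi_drivers
#' @export
autoplot.ffi_drivers <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci95_lower,
                                       xend = .data$ci95_upper,
                                       yend = .data$term), linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci90_lower,
                                       xend = .data$ci90_upper,
                                       yend = .data$term), linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "standardized coefficient (dot, 90% thick / 95% thin CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
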