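#' Tile a forest map into square analysis cells
#'
#' Divides the raster extent into non-overlapping square cells ("landscapes")
#' of `cell_size` metres on a side, the unit at which all fragmentation
#' metrics are computed. `cell_size` must be an integer multiple of the pixel
#' size so that cell windows align exactly with pixel boundaries; real-data
#' users whose grid does not divide evenly should snap the cell size or
#' resample the pixels beforehand. Partial cells left over at the right and
#' bottom edges cover less ground than `cell_size^2` (the denominator of the
#' density metrics) and are excluded unless `keep_partial = TRUE`, in which
#' case they are retained and flagged.
#'
#' @param map A [forest_map()].
#' @param cell_size Cell side length in metres (the landscape grain;
#'   5000 m for a 5 km analysis grid).
#' @param keep_partial Keep flagged partial boundary cells? Default `FALSE`.
#' @return A tibble of class `analysis_grid`, one row per cell, with 1-based
#'   inclusive pixel ranges `row_min:row_max`, `col_min:col_max`, the cell's
#'   grid position, its projected centre coordinates, `partial` flag and
#'   ground area `area_m2`. Cell ids are row-major from the top-left.
#' @examples
#' m <- forest_map(matrix(1, 100, 100), pixel_size = 50)
#' build_grid(m, cell_size = 1000)
#' @export
build_grid <- function(map, cell_size, keep_partial = FALSE) {
  stopifnot(inherits(map, "forest_map"))
  px <- map$pixel_size
  ratio <- cell_size / px
  if (cell_size <= 0 || abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf(
      "`cell_size` (%g m) must be a positive integer multiple of the pixel size (%g m).",
      cell_size, px
    ))
  }
  k <- as.integer(round(ratio))
  nr <- nrow(map$values)
  nc <- ncol(map$values)
  n_grow <- ceiling(nr / k)
  n_gcol <- ceiling(nc / k)
  g <- tidyr::expand_grid(grid_row = seq_len(n_grow), grid_col = seq_len(n_gcol))
  g <- dplyr::mutate(g,
    cell_id = dplyr::row_number(),
    row_min = (.data$grid_row - 1L) * k + 1L,
    row_max = pmin(.data$grid_row * k, nr),
    col_min = (.data$grid_col - 1L) * k + 1L,
    col_max = pmin(.data$grid_col * k, nc),
    partial = (.data$row_max - .data$row_min + 1L) < k |
      (.data$col_max - .data$col_min + 1L) < k,
    area_m2 = (.data$row_max - .data$row_min + 1) *
      (.data$col_max - .data$col_min + 1) * px^2,
    x_center = map$origin[1] +
      ((.data$col_min + .data$col_max) / 2 - 0.5) * px,
    y_center = map$origin[2] -
      ((.data$row_min + .data$row_max) / 2 - 0.5) * px
  )
  g <- dplyr::relocate(g, "cell_id")
  if (!keep_partial) g <- dplyr::filter(g, !.data$partial)
  attr(g, "cell_size") <- cell_size
  attr(g, "pixel_size") <- px
  class(g) <- c("analysis_grid", class(g))
  g
}

grid_cell_size <- function(grid) {
  cs <- attr(grid, "cell_size")
  if (is.null(cs)) abort("`grid` must be built with build_grid().")
  cs
}

#' Assign a zone label to every analysis cell
#'
#' Reduces a pixel-level categorical zone raster (climate zones, countries,
#' altitude bands, ...) to one code per analysis cell by majority vote over
#' the cell's non-nodata pixels; ties break to the smallest code.
#'
#' @param zone_map A [forest_map()]-like object whose `values` matrix holds
#'   integer category codes (constructed with [forest_map()] binarization
#'   bypassed; use [zone_map()]), or a plain integer matrix co-registered
#'   with the analysis map.
#' @param grid An [build_grid()] analysis grid.
#' @param labels Optional named character vector mapping codes to names.
#' @return Tibble `cell_id`, `zone_code`, `zone`.
#' @export
zones_from_map <- function(zone_map, grid, labels = NULL) {
  vals <- if (inherits(zone_map, "forest_map")) zone_map$values else zone_map
  stopifnot(is.matrix(vals))
  zc <- purrr::pmap_int(
    list(grid$row_min, grid$row_max, grid$col_min, grid$col_max),
    function(r0, r1, c0, c1) {
      w <- vals[r0:r1, c0:c1]
      w <- w[!is.na(w)]
      if (!length(w)) return(NA_integer_)
      tab <- table(w)
      as.integer(names(tab)[which.max(tab)])
    }
  )
  out <- tibble::tibble(cell_id = grid$cell_id, zone_code = zc)
  out$zone <- if (is.null(labels)) as.character(zc) else
    unname(labels[as.character(zc)])
  out
}

#' Construct a categorical zone raster
#'
#' Like [forest_map()] but for integer category codes (no binarization).
#'
#' @inheritParams forest_map
#' @param values Integer matrix of category codes (`NA` = nodata).
#' @return A `forest_map`-classed object holding codes.
#' @export
zone_map <- function(values, pixel_size, origin = c(0, 0),
                     crs = "local_equal_area") {
  stopifnot(is.matrix(values))
  v <- values
  storage.mode(v) <- "integer"
  structure(
    list(values = v, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), crs = as.character(crs), epoch = NA),
    class = "forest_map"
  )
}
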