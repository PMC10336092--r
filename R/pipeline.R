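# Orchestration: run the whole analysis from a config, with reproducible,
# hashed outputs, and run the simulator from a scenario spec.

#' Read a scenario spec from YAML
#'
#' @param path YAML file with the [scenario_spec()] fields (`nrow`, `ncol`,
#'   `pixel_size`, `p`, `autocorr`, `seed`, `epochs`, and `schedule` as a
#'   list of `operator`/`intensity`/`region` entries).
#' @return A validated [scenario_spec()].
#' @export
read_scenario_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  sched <- purrr::map(raw$schedule %||% list(), function(st) {
    list(operator = st$operator, intensity = st$intensity,
         region = if (!is.null(st$region)) as.integer(unlist(st$region)))
  })
  scenario_spec(
    nrow = raw$nrow, ncol = raw$ncol,
    pixel_size = raw$pixel_size %||% 30,
    p = raw$p %||% 0.4, autocorr = raw$autocorr %||% 0.7,
    schedule = sched, seed = raw$seed %||% 1,
    epochs = raw$epochs %||% c(2000, 2020),
    origin = raw$origin %||% c(0, 0)
  )
}

#' Simulate a scenario and write its files
#'
#' Runs [generate_scenario()] and writes the two epoch maps as AAIGrid plus
#' the truth table as CSV — the same formats the analysis pipeline reads.
#' Byte-identical outputs are produced for identical spec + seed.
#'
#' @param spec A [scenario_spec()] or path to a YAML spec.
#' @param out_dir Output directory (created if needed).
#' @return Tibble `file`, `path` of written artifacts, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- generate_scenario(spec)
  p1 <- file.path(out_dir, sprintf("forest_%s.asc", sc$map_1$epoch))
  p2 <- file.path(out_dir, sprintf("forest_%s.asc", sc$map_2$epoch))
  pt <- file.path(out_dir, "truth.csv")
  write_forest_map(sc$map_1, p1)
  write_forest_map(sc$map_2, p2)
  write.csv(sc$truth, pt, row.names = FALSE)
  invisible(tibble::tibble(file = c("map_1", "map_2", "truth"),
                           path = c(p1, p2, pt)))
}

#' Write a per-cell layer as an AAIGrid raster at cell resolution
#'
#' @param grid An [build_grid()] grid.
#' @param values Numeric vector aligned with `grid$cell_id`.
#' @param path Output `.asc` path.
#' @param origin Upper-left corner of the raster (defaults to pixel origin
#'   implied by the grid coordinates).
#' @return `path`, invisibly.
#' @export
write_cell_layer <- function(grid, values, path, origin = NULL) {
  stopifnot(nrow(grid) == length(values))
  cs <- grid_cell_size(grid)
  nr <- max(grid$grid_row)
  nc <- max(grid$grid_col)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(grid$grid_row, grid$grid_col)] <- values
  if (is.null(origin)) {
    origin <- c(min(grid$x_center) - cs / 2, max(grid$y_center) + cs / 2)
  }
  m[is.na(m)] <- -9999
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2] - nr * cs),
           sprintf("cellsize %.10g", cs), "NODATA_value -9999")
  writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
  invisible(path)
}

validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("forest_1", "forest_2", "cell_size", "out_dir")
  missing_f <- setdiff(req, names(config))
  if (length(missing_f)) {
    abort(paste("Config is missing field(s):", paste(missing_f, collapse = ", ")))
  }
  defaults <- list(connectivity = 8, count_boundary = FALSE,
                   max_nodata_frac = 0.5, clip_percentiles = c(0, 100),
                   weights = c(1, 1, 1) / 3, tie = "down", stable_eps = 0.005,
                   epochs = c(1, 2), zones = NULL, zone_labels = NULL,
                   drivers = NULL, coarse_size = NULL, n_min = 30, seed = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  check_connectivity(config$connectivity)
  if (!config$tie %in% c("down", "exclude")) {
    abort("`tie` must be 'down' or 'exclude'.")
  }
  if (length(config$weights) != 3 || any(config$weights < 0) ||
      abs(sum(config$weights) - 1) > 1e-9) {
    abort("`weights` must be 3 non-negative values summing to 1.")
  }
  if (length(config$clip_percentiles) != 2 ||
      config$clip_percentiles[1] >= config$clip_percentiles[2]) {
    abort("`clip_percentiles` must be an increasing pair in [0, 100].")
  }
  config
}

load_map <- function(x, epoch) {
  if (inherits(x, "forest_map")) {
    if (!is.null(epoch) && !is.na(epoch)) x$epoch <- epoch
    return(x)
  }
  read_forest_map(x, epoch = epoch)
}

#' Run the full fragmentation analysis pipeline
#'
#' Sequences the whole analysis: read and co-register the two epoch maps,
#' tile the extent, compute per-cell metrics for both epochs, fit pooled
#' normalization and compose the index layers, classify modes and patterns,
#' tabulate compositions, and (optionally) summarize over zones and fit the
#' driver model with its coarse-grid major-driver map. Every artifact is
#' written to `out_dir` together with the verbatim config and a JSON
#' manifest of content hashes; rerunning with identical inputs and config
#' reproduces the hashes.
#'
#' The config is a named list or YAML path with required fields `forest_1`,
#' `forest_2` (AAIGrid paths or [forest_map()] objects), `cell_size` and
#' `out_dir`, plus the optional knobs `epochs`, `connectivity`,
#' `count_boundary`, `max_nodata_frac`, `clip_percentiles`, `weights`,
#' `tie`, `stable_eps`, `zones` (AAIGrid path, [zone_map()] or
#' `cell_id`/`zone` table), `zone_labels`, `drivers` (CSV path or table),
#' `coarse_size`, `n_min`, `seed`.
#'
#' @param config Named list or YAML file path.
#' @return List of class `ffi_pipeline`: the in-memory results
#'   (`grid`, `metrics`, `layers`, `classified`, `mode_composition`,
#'   `zonal`, `drivers_fit`, `major_drivers`) plus `manifest`
#'   (tibble `file`, `path`, `md5`).
#' @export
run_ffi_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  map_1 <- stage("read", load_map(config$forest_1, config$epochs[1]))
  map_2 <- stage("read", load_map(config$forest_2, config$epochs[2]))
  coreg <- check_coregistration(map_1, map_2)
  if (!coreg$ok) {
    abort(paste("Input maps are not co-registered; mismatched:",
                paste(coreg$mismatches$field, collapse = ", ")))
  }
  grid <- stage("grid", build_grid(map_1, config$cell_size))
  metrics <- stage("metrics", dplyr::bind_rows(
    compute_metrics_grid(map_1, grid, config$connectivity,
                         config$count_boundary, config$max_nodata_frac),
    compute_metrics_grid(map_2, grid, config$connectivity,
                         config$count_boundary, config$max_nodata_frac)
  ))
  layers <- stage("index", ffi_layers(metrics,
                                      clip_percentiles = config$clip_percentiles,
                                      weights = config$weights))
  classified <- stage("classify", classify_changes(layers, tie = config$tie,
                                                   stable_eps = config$stable_eps))
  comp <- stage("classify", mode_composition(classified))

  artifacts <- list()
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    artifacts[[length(artifacts) + 1]] <<- tibble::tibble(file = name, path = path)
  }
  put("metrics.csv", function(p) write.csv(metrics, p, row.names = FALSE))
  put("norm_params.yml", function(p) write_norm_params(attr(layers, "norm_params"), p))
  put("ffi_layers.csv", function(p) write.csv(as.data.frame(layers), p, row.names = FALSE))
  put("classified.csv", function(p) write.csv(as.data.frame(classified), p, row.names = FALSE))
  put("mode_composition.csv", function(p) write.csv(comp, p, row.names = FALSE))
  lay_grid <- grid[grid$cell_id %in% classified$cell_id, ]
  ord <- match(lay_grid$cell_id, classified$cell_id)
  for (vn in c("ffi_1", "ffi_2", "d_ffi", "d_fc")) {
    local({
      v <- classified[[vn]][ord]
      put(paste0(vn, ".asc"), function(p) write_cell_layer(lay_grid, v, p))
    })
  }

  zonal <- NULL
  if (!is.null(config$zones)) {
    zones <- stage("zones", {
      z <- config$zones
      if (is.character(z)) z <- read_zone_raster(z)
      if (inherits(z, "forest_map") || is.matrix(z)) {
        zones_from_map(z, grid, labels = config$zone_labels)
      } else {
        tibble::as_tibble(z)
      }
    })
    zonal <- stage("zones", zonal_summary(classified, zones,
                                          cell_area = config$cell_size^2))
    put("zonal_stats.csv", function(p) write.csv(zonal$stats, p, row.names = FALSE))
    put("zonal_pattern_shares.csv",
        function(p) write.csv(zonal$pattern_shares, p, row.names = FALSE))
    put("zonal_mode_shares.csv",
        function(p) write.csv(zonal$mode_shares, p, row.names = FALSE))
  }

  drivers_fit <- NULL
  major <- NULL
  if (!is.null(config$drivers)) {
    drv <- stage("drivers", {
      d <- config$drivers
      if (is.character(d)) d <- read.csv(d)
      d <- tibble::as_tibble(d)
      if (!"d_ffi" %in% names(d)) {
        d <- dplyr::inner_join(d, dplyr::select(classified, "cell_id", "d_ffi"),
                               by = "cell_id")
      }
      d
    })
    drivers_fit <- stage("drivers", fit_ffi_drivers(drv))
    put("driver_coefficients.csv",
        function(p) write.csv(tidy(drivers_fit), p, row.names = FALSE))
    put("driver_model.json", function(p) jsonlite::write_json(
      list(coefficients = tidy(drivers_fit), fit = glance(drivers_fit)),
      p, auto_unbox = TRUE, digits = NA))
    if (!is.null(config$coarse_size) && all(c("x", "y") %in% names(drv))) {
      major <- stage("drivers", major_driver_map(
        drv, config$coarse_size, config$cell_size, n_min = config$n_min))
      put("major_drivers.csv", function(p) write.csv(major, p, row.names = FALSE))
    }
  }

  cfg_out <- config
  cfg_out$forest_1 <- if (is.character(config$forest_1)) config$forest_1 else "<in-memory map>"
  cfg_out$forest_2 <- if (is.character(config$forest_2)) config$forest_2 else "<in-memory map>"
  cfg_out$zones <- if (is.character(config$zones)) config$zones else
    if (is.null(config$zones)) NULL else "<in-memory zones>"
  cfg_out$drivers <- if (is.character(config$drivers)) config$drivers else
    if (is.null(config$drivers)) NULL else "<in-memory table>"
  put("config.yml", function(p) yaml::write_yaml(cfg_out, p))

  manifest <- dplyr::bind_rows(artifacts)
  manifest$md5 <- unname(tools::md5sum(manifest$path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(grid = grid, metrics = metrics, layers = layers,
                 classified = classified, mode_composition = comp,
                 zonal = zonal, drivers_fit = drivers_fit,
                 major_drivers = major, manifest = manifest),
            class = "ffi_pipeline")
}

#' @export
print.ffi_pipeline <- function(x, ...) {
  cat(sprintf("<ffi_pipeline> %d cells, %d artifacts written\n",
              nrow(x$layers), nrow(x$manifest)))
  print(x$manifest)
  invisible(x)
}

# Zone rasters are AAIGrid too, but hold integer codes, not a binary class.
read_zone_raster <- function(path) {
  hdr <- parse_aaigrid_header(path)
  vals <- scan(path, what = double(), skip = hdr$n_header, quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.na(hdr$nodata)) m[m == hdr$nodata] <- NA
  zone_map(m, pixel_size = hdr$cellsize,
           origin = c(hdr$xll, hdr$yll + hdr$nrows * hdr$cellsize))
}
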