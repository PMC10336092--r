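#' Specify a synthetic bi-temporal landscape scenario
#'
#' Bundles and validates everything the simulator needs: extent, pixel size,
#' target initial forest proportion `p`, an autocorrelation knob in `[0, 1)`
#' (higher = fewer seed nuclei, hence larger and fewer patches at equal
#' cover), a schedule of change operators applied in order to produce the
#' second epoch, and a seed. Identical spec + seed gives identical outputs.
#'
#' @param nrow,ncol Extent in pixels.
#' @param pixel_size Pixel side length, metres (default 30).
#' @param p Initial forest proportion, in (0, 1).
#' @param autocorr Cluster-growth autocorrelation in `[0, 1)`.
#' @param schedule List of steps, each `list(operator =, intensity =, region
#'   = NULL)`; `region` is `c(row_min, row_max, col_min, col_max)` in pixels
#'   or `NULL` for the whole map. Operators: `edge_erosion`, `dissection`,
#'   `perforation`, `attrition`, `infill`, `seeding`, `expansion`.
#' @param seed Integer seed.
#' @param epochs Length-2 epoch labels (default `c(2000, 2020)`).
#' @param origin Projected upper-left corner coordinates.
#' @return A validated list of class `scenario_spec`.
#' @export
scenario_spec <- function(nrow, ncol, pixel_size = 30, p = 0.4,
                          autocorr = 0.7, schedule = list(), seed = 1,
                          epochs = c(2000, 2020), origin = c(0, 0)) {
  if (!(p > 0 && p < 1)) abort("`p` must lie strictly between 0 and 1.")
  if (!(autocorr >= 0 && autocorr < 1)) abort("`autocorr` must lie in [0, 1).")
  ops <- c("edge_erosion", "dissection", "perforation", "attrition",
           "infill", "seeding", "expansion")
  for (i in seq_along(schedule)) {
    st <- schedule[[i]]
    if (is.null(st$operator) || !st$operator %in% ops) {
      abort(sprintf(
        "schedule[[%d]]$operator must be one of: %s", i,
        paste(ops, collapse = ", ")))
    }
    if (is.null(st$intensity) || st$intensity < 0 || st$intensity > 1) {
      abort(sprintf("schedule[[%d]]$intensity must lie in [0, 1].", i))
    }
    if (!is.null(st$region) && length(st$region) != 4) {
      abort(sprintf(
        "schedule[[%d]]$region must be c(row_min, row_max, col_min, col_max).", i))
    }
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size = pixel_size, p = p, autocorr = autocorr,
                 schedule = schedule, seed = as.integer(seed),
                 epochs = epochs, origin = origin),
            class = "scenario_spec")
}

#' Generate a spatially autocorrelated initial forest map
#'
#' Modified-random-clusters neutral landscape: seed pixels are sprinkled at
#' density `p * (1 - autocorr)` and clusters grow by accreting random
#' non-forest neighbours (queen's case) until the realized forest proportion
#' hits the target exactly (so it is always within ±0.01 of `p`). The map
#' carries no ecological mechanism — it is a null landscape whose patch
#' structure is controlled by one autocorrelation knob.
#'
#' @param spec A [scenario_spec()].
#' @return A [forest_map()] labelled with the first epoch.
#' @export
generate_initial_map <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  nr <- spec$nrow
  nc <- spec$ncol
  total <- nr * nc
  target <- round(spec$p * total)
  with_seed(spec$seed, {
    n_seeds <- max(1L, round(total * spec$p * (1 - spec$autocorr)))
    n_seeds <- min(n_seeds, target)
    f <- matrix(0L, nr, nc)
    f[sample.int(total, n_seeds)] <- 1L
    it <- 0L
    while (sum(f) < target) {
      it <- it + 1L
      if (it > 10000L) {
        abort("Initial map generation did not reach the target proportion.")
      }
      cand <- which(f == 0L & neighbour_count(f, 8) > 0L)
      if (!length(cand)) {
        abort("No growth candidates left before reaching the target proportion.")
      }
      need <- target - sum(f)
      take <- if (length(cand) <= need) cand else sample(cand, need)
      f[take] <- 1L
    }
    forest_map(f, pixel_size = spec$pixel_size, origin = spec$origin,
               crs = "synthetic_equal_area", epoch = spec$epochs[1])
  })
}

# Expected change signs per operator (+1 increase, -1 decrease, NA not
# asserted): the ground-truth direction table for scenario checks. Only
# robust directions are asserted; operators are stochastic, so ambiguous
# effects (e.g. the edge response to boundary erosion) stay NA.
operator_truth <- function() {
  tibble::tribble(
    ~operator,      ~d_ed, ~d_pd, ~d_mpa, ~d_fc, ~d_ffi,
    "edge_erosion",    NA,    NA,     NA,    -1,     NA,
    "dissection",       1,     1,     -1,    -1,      1,
    "perforation",      1,    NA,     NA,    -1,     NA,
    "attrition",       NA,    -1,     NA,    -1,     NA,
    "infill",          -1,    -1,      1,     1,     -1,
    "seeding",         NA,     1,     NA,     1,     NA,
    "expansion",       NA,    NA,      1,     1,     NA
  )
}

#' Apply one landscape-change operator
#'
#' Mutates a binary forest map with one of the canonical spatial change
#' processes. Each operator moves forest area monotonically in its natural
#' direction:
#' \describe{
#'   \item{edge_erosion}{removes a fraction `intensity` of forest pixels that
#'     touch non-forest (shaves patch boundaries).}
#'   \item{dissection}{carves 1-pixel-wide random row/column transects
#'     through the (region's) forest, cutting patches apart.}
#'   \item{perforation}{removes a fraction of strictly interior forest
#'     pixels, opening holes.}
#'   \item{attrition}{deletes the smallest patches until a fraction
#'     `intensity` of the patch count is gone.}
#'   \item{infill}{fills non-forest pixels surrounded by forest (>= 4 of 8
#'     neighbours), closing gaps and holes and merging near patches.}
#'   \item{seeding}{plants new isolated single-pixel patches away from
#'     existing forest.}
#'   \item{expansion}{converts a fraction of all non-forest pixels adjacent
#'     to forest, growing every patch boundary.}
#' }
#' When nothing is eligible the map is returned unchanged with a warning.
#'
#' @param map A [forest_map()].
#' @param operator Operator name (see above).
#' @param intensity In `[0, 1]`; 0 is a no-op.
#' @param seed Optional integer; the operator draws from its own temporary
#'   stream so surrounding RNG state is untouched.
#' @param region Optional `c(row_min, row_max, col_min, col_max)` pixel
#'   bounds; the operator acts on that window only (patches truncated at the
#'   window, like analysis cells).
#' @return The modified [forest_map()].
#' @export
apply_operator <- function(map, operator, intensity, seed = NULL,
                           region = NULL) {
  stopifnot(inherits(map, "forest_map"))
  ops <- operator_truth()$operator
  if (!operator %in% ops) {
    abort(sprintf("Unknown operator '%s'; must be one of: %s", operator,
                  paste(ops, collapse = ", ")))
  }
  if (intensity < 0 || intensity > 1) abort("`intensity` must lie in [0, 1].")
  if (intensity == 0) return(map)
  v <- map$values
  if (is.null(region)) region <- c(1L, nrow(v), 1L, ncol(v))
  rows <- region[1]:region[2]
  cols <- region[3]:region[4]
  sub <- v[rows, cols, drop = FALSE]
  sub2 <- with_seed(seed, apply_operator_window(sub, operator, intensity))
  if (is.null(sub2)) {
    warn(sprintf("Operator '%s': nothing eligible; map unchanged.", operator))
    return(map)
  }
  v[rows, cols] <- sub2
  out <- map
  out$values <- v
  out
}

apply_operator_window <- function(v, operator, intensity) {
  forest <- !is.na(v) & v == 1L
  nonforest <- !is.na(v) & v == 0L
  take_frac <- function(cand, frac) {
    k <- round(frac * length(cand))
    if (k <= 0) return(integer(0))
    if (k >= length(cand)) cand else sample(cand, k)
  }
  switch(operator,
    edge_erosion = {
      nf <- neighbour_count(ifelse(nonforest, 1L, 0L), 4)
      cand <- which(forest & nf > 0L)
      if (!length(cand)) return(NULL)
      v[take_frac(cand, intensity)] <- 0L
      v
    },
    dissection = {
      nr <- nrow(v)
      nc <- ncol(v)
      n_t <- max(1L, round(intensity * (nr + nc) / 10))
      if (!any(forest)) return(NULL)
      for (i in seq_len(n_t)) {
        if (runif(1) < nr / (nr + nc)) {
          r <- sample.int(nr, 1)
          v[r, !is.na(v[r, ]) & v[r, ] == 1L] <- 0L
        } else {
          cc <- sample.int(nc, 1)
          v[!is.na(v[, cc]) & v[, cc] == 1L, cc] <- 0L
        }
      }
      v
    },
    perforation = {
      cand <- which(forest & neighbour_count(v, 8) == 8L)
      if (!length(cand)) return(NULL)
      v[take_frac(cand, intensity)] <- 0L
      v
    },
    attrition = {
      lab <- label_patches(v, connectivity = 8)
      if (lab$n_patches == 0) return(NULL)
      k <- floor(intensity * lab$n_patches + 1e-9)
      if (k == 0) return(v)
      doomed <- order(lab$patch_areas_px)[seq_len(k)]
      v[lab$labels %in% doomed] <- 0L
      v
    },
    infill = {
      changed <- FALSE
      for (round in 1:5) {
        nonf <- !is.na(v) & v == 0L
        cand <- which(nonf & neighbour_count(v, 8) >= 4L)
        if (!length(cand)) break
        pick <- take_frac(cand, intensity)
        if (!length(pick)) break
        v[pick] <- 1L
        changed <- TRUE
      }
      if (!changed) return(NULL)
      v
    },
    seeding = {
      cand <- which(nonforest & neighbour_count(v, 8) == 0L)
      if (!length(cand)) return(NULL)
      k <- max(1L, round(intensity * length(cand) * 0.02))
      v[if (k >= length(cand)) cand else sample(cand, k)] <- 1L
      v
    },
    expansion = {
      cand <- which(nonforest & neighbour_count(v, 8) >= 1L)
      if (!length(cand)) return(NULL)
      v[take_frac(cand, intensity)] <- 1L
      v
    }
  )
}

#' Generate a bi-temporal scenario with known change processes
#'
#' Builds the first-epoch map with [generate_initial_map()], then applies
#' the operator schedule to produce the second epoch. Each scheduled
#' operator application draws from its own random stream derived from
#' `(seed, schedule index)`, so inserting a step does not perturb the draws
#' of later steps. The returned truth table records, per step, the expected
#' direction of each metric and of coverage and fragmentation change from
#' the fixed operator-effect table (directions not robustly implied by an
#' operator are `NA`).
#'
#' @param spec A [scenario_spec()].
#' @return List: `map_1`, `map_2` ([forest_map()]s) and `truth` (tibble with
#'   `step`, `operator`, `intensity`, region bounds and expected signs
#'   `d_ed`, `d_pd`, `d_mpa`, `d_fc`, `d_ffi` in `{-1, 1, NA}`).
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  map_1 <- generate_initial_map(spec)
  map_2 <- map_1
  map_2$epoch <- spec$epochs[2]
  truth_rows <- list()
  tt <- operator_truth()
  for (i in seq_along(spec$schedule)) {
    st <- spec$schedule[[i]]
    map_2 <- apply_operator(map_2, st$operator, st$intensity,
                            seed = derive_seed(spec$seed, i),
                            region = st$region)
    reg <- st$region %||% c(1L, spec$nrow, 1L, spec$ncol)
    truth_rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(step = i, operator = st$operator,
                     intensity = st$intensity,
                     row_min = reg[1], row_max = reg[2],
                     col_min = reg[3], col_max = reg[4]),
      dplyr::select(tt[tt$operator == st$operator, ], -"operator")
    )
  }
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
    tibble::tibble(step = integer(), operator = character(),
                   intensity = numeric(), row_min = integer(),
                   row_max = integer(), col_min = integer(),
                   col_max = integer(), d_ed = numeric(), d_pd = numeric(),
                   d_mpa = numeric(), d_fc = numeric(), d_ffi = numeric())
  list(map_1 = map_1, map_2 = map_2, truth = truth)
}

# Smooth standard-normal field via bilinear interpolation of a coarse
# iid-normal lattice; `scale` is the correlation length in cells.
smooth_field <- function(nr, nc, scale = 8) {
  cr <- ceiling(nr / scale) + 1L
  cc <- ceiling(nc / scale) + 1L
  z <- matrix(rnorm(cr * cc), cr, cc)
  ri <- (seq_len(nr) - 1) / scale + 1
  ci <- (seq_len(nc) - 1) / scale + 1
  r0 <- pmin(floor(ri), cr - 1L)
  c0 <- pmin(floor(ci), cc - 1L)
  fr <- ri - r0
  fc <- ci - c0
  (1 - fr) %o% (1 - fc) * z[r0, c0] + (1 - fr) %o% fc * z[r0, c0 + 1] +
    fr %o% (1 - fc) * z[r0 + 1, c0] + fr %o% fc * z[r0 + 1, c0 + 1]
}

#' Generate driver covariate fields with planted linear effects
#'
#' Simulates the seven driver covariates as smooth spatial fields on a cell
#' grid, min–max rescales them to `[0, 1]`, and generates the response as
#' the planted linear combination plus Gaussian noise:
#' `d_ffi = sum_j beta_j * x_j + N(0, noise_sd)`. The planted coefficients
#' are recorded so regression recovery can be checked against truth.
#'
#' @param n_row,n_col Cell-grid dimensions (n = n_row * n_col cells).
#' @param coefficients Length-7 numeric, in [driver_names()] order.
#' @param noise_sd Gaussian noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @param cell_size Cell size in metres, used for the `x`, `y` cell-centre
#'   coordinates (default 5000).
#' @param smooth_scale Correlation length of the fields, in cells.
#' @return Tibble `cell_id`, `x`, `y`, the seven covariates and `d_ffi`;
#'   planted coefficients attached as attribute `truth`.
#' @export
generate_driver_fields <- function(n_row, n_col, coefficients,
                                   noise_sd = 0.05, seed = 1,
                                   cell_size = 5000, smooth_scale = 8) {
  if (length(coefficients) != 7) {
    abort("`coefficients` must have length 7 (one per driver).")
  }
  nms <- driver_names()
  with_seed(seed, {
    covs <- purrr::map(setNames(nms, nms), function(nm) {
      f <- as.vector(smooth_field(n_row, n_col, smooth_scale))
      (f - min(f)) / (max(f) - min(f))
    })
    grid <- tidyr::expand_grid(row = seq_len(n_row), col = seq_len(n_col))
    out <- tibble::tibble(
      cell_id = seq_len(n_row * n_col),
      x = (grid$col - 0.5) * cell_size,
      y = (n_row - grid$row + 0.5) * cell_size
    )
    for (nm in nms) out[[nm]] <- covs[[nm]]
    x_mat <- as.matrix(out[, nms])
    out$d_ffi <- as.vector(x_mat %*% coefficients) +
      rnorm(nrow(out), 0, noise_sd)
    attr(out, "truth") <- setNames(as.numeric(coefficients), nms)
    out
  })
}

#' Build a driver table from covariate rasters
#'
#' Raster-to-table helper for real covariate inputs: per analysis cell it
#' takes the two-epoch mean and difference of cropland coverage, nighttime
#' light and population density rasters, and the mean burned fraction as
#' fire frequency. Any raster may be omitted (`NULL`), leaving its columns
#' out.
#'
#' @param grid An [build_grid()] grid.
#' @param cropland,light,popdens Each `NULL` or a list of two co-registered
#'   continuous matrices/[forest_map()]s (epoch 1, epoch 2).
#' @param fire `NULL` or one matrix of burned fraction/counts.
#' @return Tibble keyed by `cell_id` with `x`, `y` and the available driver
#'   columns, ready for [fit_ffi_drivers()].
#' @export
build_driver_table <- function(grid, cropland = NULL, light = NULL,
                               popdens = NULL, fire = NULL) {
  as_mat <- function(m) if (inherits(m, "forest_map")) m$values else m
  cell_mean <- function(m) {
    purrr::pmap_dbl(
      list(grid$row_min, grid$row_max, grid$col_min, grid$col_max),
      function(r0, r1, c0, c1) mean(m[r0:r1, c0:c1], na.rm = TRUE)
    )
  }
  out <- tibble::tibble(cell_id = grid$cell_id, x = grid$x_center,
                        y = grid$y_center)
  pair <- function(lst, mean_name, change_name) {
    m1 <- cell_mean(as_mat(lst[[1]]))
    m2 <- cell_mean(as_mat(lst[[2]]))
    out[[mean_name]] <<- (m1 + m2) / 2
    out[[change_name]] <<- m2 - m1
  }
  if (!is.null(cropland)) pair(cropland, "cropland_mean", "cropland_change")
  if (!is.null(light)) pair(light, "light_mean", "light_change")
  if (!is.null(popdens)) pair(popdens, "popdens_mean", "popdens_change")
  if (!is.null(fire)) out$fire_freq <- cell_mean(as_mat(fire))
  out
}
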