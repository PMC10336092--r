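# Independent brute-force oracles, deliberately written without reusing any
# package internals: plain R loops and an explicit flood-fill stack.

# Flood-fill connected-component count and areas.
oracle_label <- function(w, connectivity = 8) {
  nr <- nrow(w)
  nc <- ncol(w)
  forest <- !is.na(w) & w == 1
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  areas <- integer(0)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (forest[i, j] && !seen[i, j]) {
        stack <- list(c(i, j))
        seen[i, j] <- TRUE
        area <- 0L
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          area <- area + 1L
          for (k in seq_len(nrow(nb))) {
            r <- p[1] + nb[k, 1]
            cc <- p[2] + nb[k, 2]
            if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
                forest[r, cc] && !seen[r, cc]) {
              seen[r, cc] <- TRUE
              stack[[length(stack) + 1]] <- c(r, cc)
            }
          }
        }
        areas <- c(areas, area)
      }
    }
  }
  list(n_patches = length(areas), areas = areas)
}

# Exhaustive enumeration of forest/non-forest 4-adjacencies.
oracle_edge <- function(w, pixel_size, count_boundary = FALSE) {
  nr <- nrow(w)
  nc <- ncol(w)
  n <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- w[i, j]
      if (is.na(v)) next
      if (i < nr && !is.na(w[i + 1, j]) && v + w[i + 1, j] == 1) n <- n + 1L
      if (j < nc && !is.na(w[i, j + 1]) && v + w[i, j + 1] == 1) n <- n + 1L
      if (count_boundary && v == 1) {
        n <- n + (i == 1) + (i == nr) + (j == 1) + (j == nc)
      }
    }
  }
  n * pixel_size
}

# Metrics straight from the defining equations, using the two oracles above.
oracle_metrics <- function(w, pixel_size, cell_area, connectivity = 8,
                           count_boundary = FALSE) {
  lab <- oracle_label(w, connectivity)
  fp <- sum(lab$areas)
  list(
    ed = oracle_edge(w, pixel_size, count_boundary) / cell_area * 10000,
    pd = lab$n_patches / cell_area * 10000 * 100,
    mpa = if (lab$n_patches > 0)
      fp * pixel_size^2 / 10000 / lab$n_patches else NA_real_,
    fc = fp * pixel_size^2 / cell_area,
    n_patches = lab$n_patches
  )
}

# Sort-based percentile (linear interpolation between order statistics,
# matching the default sample-quantile definition).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_window <- function(nr, nc, p = 0.5) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

# Random two-epoch metrics table with plausible scales, for index-property
# tests (a fraction of cells non-forest in one or both epochs).
random_metrics_table <- function(n_cells, epochs = c(2000, 2020),
                                 p_nonforest = 0.1) {
  purrr::map_dfr(epochs, function(ep) {
    forest <- runif(n_cells) > p_nonforest
    tibble::tibble(
      cell_id = seq_len(n_cells),
      epoch = ep,
      ed = ifelse(forest, runif(n_cells, 0, 120), 0),
      pd = ifelse(forest, runif(n_cells, 0, 400), 0),
      mpa = ifelse(forest, exp(runif(n_cells, log(0.01), log(100))), NA),
      fc = ifelse(forest, runif(n_cells, 0.01, 1), 0),
      forest_pixels = ifelse(forest, 10L, 0L),
      e_total = 0,
      n_patches = ifelse(forest, 1L, 0L),
      forest = forest
    )
  })
}

# small reference helper used above: 8-neighbour forest counts, written
# independently of the package internals
neighbour_count_ref <- function(w) {
  nr <- nrow(w)
  nc <- ncol(w)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      r <- i + di
      cc <- j + dj
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
          !is.na(w[r, cc]) && w[r, cc] == 1) {
        out[i, j] <- out[i, j] + 1L
      }
    }
  }
  out
}
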