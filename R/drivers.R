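#' Canonical driver covariate names
#'
#' Seven factors: agricultural activity (mean cropland coverage and its
#' change), socio-economic intensity (mean nighttime light and its change),
#' demographic pressure (mean population density and its change) and natural
#' disturbance (fire frequency).
#'
#' @return Character vector of the seven column names.
#' @export
driver_names <- function() {
  c("cropland_mean", "cropland_change", "light_mean", "light_change",
    "popdens_mean", "popdens_change", "fire_freq")
}

#' Rescale columns to the unit interval
#'
#' Min–max standardization `x' = (x - min) / (max - min)` applied per
#' column, so coefficients of a linear model fitted on the result are
#' comparable across covariates ("standardized coefficients" in the 0-1
#' sense). Ranges are computed over the rows actually supplied, which should
#' be the fitted subset (standardize after dropping incomplete rows, not
#' before, to avoid leaking dropped rows into the scale).
#'
#' @param data A data frame.
#' @param cols Columns to rescale; default all numeric columns except
#'   `cell_id`, `x`, `y`.
#' @return `data` with the selected columns rescaled; the ranges used are
#'   attached as attribute `ranges`.
#' @export
standardize_01 <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    c("cell_id", "x", "y"))
  }
  ranges <- purrr::map(setNames(cols, cols), function(cl) {
    r <- range(data[[cl]], na.rm = TRUE)
    if (!(r[1] < r[2])) {
      abort(sprintf("Column '%s' is constant; cannot rescale to [0, 1].", cl))
    }
    r
  })
  for (cl in cols) {
    r <- ranges[[cl]]
    data[[cl]] <- (data[[cl]] - r[1]) / (r[2] - r[1])
  }
  attr(data, "ranges") <- ranges
  data
}

#' Fit a standardized linear driver model of fragmentation change
#'
#' Ordinary least squares (a general linear model with identity link and
#' Gaussian errors) of the index change on the driver covariates, with the
#' response and every covariate min–max rescaled to `[0, 1]` on the fitted
#' rows. Rows with any missing value are dropped and counted. Confidence
#' intervals use the conventional multipliers: 90% = ±1.645 SE,
#' 95% = ±1.960 SE.
#'
#' @param data Tibble with the response column and covariate columns.
#' @param response Name of the response column (default `"d_ffi"`).
#' @param covariates Covariate column names; default [driver_names()]
#'   intersected with `data`, or all remaining numeric columns.
#' @param standardize Rescale response and covariates to `[0, 1]` first?
#'   Default `TRUE`; set `FALSE` if the table is already standardized.
#' @return Object of class `ffi_drivers` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(x1 = runif(100), x2 = runif(100))
#' d$d_ffi <- 0.4 * d$x1 - 0.2 * d$x2 + rnorm(100, 0, 0.03)
#' fit <- fit_ffi_drivers(d)
#' tidy(fit)
#' @export
fit_ffi_drivers <- function(data, response = "d_ffi", covariates = NULL,
                            standardize = TRUE) {
  if (is.null(covariates)) {
    covariates <- intersect(driver_names(), names(data))
    if (!length(covariates)) {
      covariates <- setdiff(
        names(data)[vapply(data, is.numeric, logical(1))],
        c(response, "cell_id", "x", "y"))
    }
  }
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  d <- data[, c(response, covariates)]
  complete <- stats::complete.cases(d)
  n_dropped <- sum(!complete)
  d <- d[complete, ]
  if (nrow(d) <= length(covariates) + 1) {
    abort(sprintf("Need n > %d rows to fit %d covariates; have %d complete.",
                  length(covariates) + 1, length(covariates), nrow(d)))
  }
  if (standardize) d <- standardize_01(d, cols = c(response, covariates))
  x <- as.matrix(d[, covariates])
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    dropped_terms <- c("(intercept)", covariates)[-seq_len(qrx$rank)]
    kept <- c("(intercept)", covariates)[qrx$pivot[seq_len(qrx$rank)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(setdiff(c("(intercept)", covariates), kept),
                       collapse = ", ")))
  }
  fml <- stats::reformulate(covariates, response = response)
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    statistic = unname(ct[, 3]),
    p_value = unname(ct[, 4]),
    ci90_lower = unname(ct[, 1] - 1.645 * ct[, 2]),
    ci90_upper = unname(ct[, 1] + 1.645 * ct[, 2]),
    ci95_lower = unname(ct[, 1] - 1.960 * ct[, 2]),
    ci95_upper = unname(ct[, 1] + 1.960 * ct[, 2])
  )
  structure(
    list(coefs = coefs, fit = fit, n = nrow(d), n_dropped = n_dropped,
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma, response = response, covariates = covariates),
    class = "ffi_drivers"
  )
}

#' @export
print.ffi_drivers <- function(x, ...) {
  cat(sprintf("<ffi_drivers> OLS of %s on %d standardized covariates, n = %d (%d dropped), R2 = %.3f\n",
              x$response, length(x$covariates), x$n, x$n_dropped, x$r_squared))
  print(x$coefs)
  invisible(x)
}

#' @method tidy ffi_drivers
#' @export
tidy.ffi_drivers <- function(x, ...) x$coefs

#' @method glance ffi_drivers
#' @export
glance.ffi_drivers <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 sigma = x$sigma, n = x$n, n_dropped = x$n_dropped)
}

#' Coarse-grid map of the major driver of fragmentation change
#'
#' Aggregates analysis cells into coarse square blocks (e.g. 50 km on a 5 km
#' cell grid), fits the standardized driver model within each block and
#' reports the covariate with the largest absolute coefficient — the block's
#' "major driver". Blocks with fewer than `n_min` complete rows, or where
#' the fit fails (e.g. a constant covariate within the block), yield `NA`.
#'
#' @param data Tibble with `x`, `y` cell-centre coordinates, the response and
#'   covariate columns.
#' @param coarse_size Block side length in metres; must be an integer
#'   multiple of `cell_size`.
#' @param cell_size Analysis cell size in metres.
#' @param n_min Minimum rows per block (default 30).
#' @inheritParams fit_ffi_drivers
#' @return Tibble: `coarse_row`, `coarse_col`, `n`, `major_driver`,
#'   `coefficient` (the signed winning estimate; `NA` where unfit).
#' @export
major_driver_map <- function(data, coarse_size, cell_size,
                             response = "d_ffi", covariates = NULL,
                             n_min = 30) {
  ratio <- coarse_size / cell_size
  if (abs(ratio - round(ratio)) > 1e-9 || coarse_size <= 0) {
    abort("`coarse_size` must be a positive integer multiple of `cell_size`.")
  }
  stopifnot(all(c("x", "y") %in% names(data)))
  d <- dplyr::mutate(data,
    coarse_col = floor((.data$x - min(.data$x)) / coarse_size) + 1L,
    coarse_row = floor((max(.data$y) - .data$y) / coarse_size) + 1L
  )
  groups <- dplyr::group_split(dplyr::group_by(d, .data$coarse_row, .data$coarse_col))
  purrr::map_dfr(groups, function(g) {
    base <- tibble::tibble(coarse_row = g$coarse_row[1],
                           coarse_col = g$coarse_col[1], n = nrow(g),
                           major_driver = NA_character_,
                           coefficient = NA_real_)
    if (nrow(g) < n_min) return(base)
    fit <- tryCatch(
      fit_ffi_drivers(g, response = response, covariates = covariates),
      error = function(e) NULL
    )
    if (is.null(fit)) return(base)
    slopes <- dplyr::filter(fit$coefs, .data$term != "(Intercept)")
    win <- slopes[which.max(abs(slopes$estimate)), ]
    base$major_driver <- win$term
    base$coefficient <- win$estimate
    base
  })
}
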