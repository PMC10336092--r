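#' Fit normalization bounds for the fragmentation metrics
#'
#' The three raw metrics live on different scales, so the fragmentation index
#' is built from normalized values. Bounds are taken as percentiles of the
#' POOLED two-epoch distribution over forest cells — fitting per epoch would
#' destroy the comparability of the index between years, because a cell with
#' unchanged metrics could change index value. The default `clip_percentiles
#' = c(0, 100)` is plain min–max; `c(0.5, 99.5)` gives outlier-robust bounds
#' (values beyond the bounds are clamped during normalization).
#'
#' @param metrics Output of [compute_metrics_grid()] for both epochs, row-bound.
#' @param clip_percentiles Length-2 percentages in `[0, 100]`.
#' @return Tibble of class `ffi_norm_params`: `metric`, `lower`, `upper`.
#' @export
fit_normalization <- function(metrics, clip_percentiles = c(0, 100)) {
  stopifnot(length(clip_percentiles) == 2, clip_percentiles[1] < clip_percentiles[2])
  f <- dplyr::filter(metrics, .data$forest)
  if (nrow(f) < 2) abort("Need at least 2 forest cells to fit normalization bounds.")
  params <- purrr::map_dfr(c("ed", "pd", "mpa"), function(m) {
    x <- f[[m]]
    x <- x[!is.na(x)]
    b <- unname(quantile(x, clip_percentiles / 100, type = 7))
    if (!(b[1] < b[2])) {
      abort(sprintf(
        "Degenerate normalization bounds for '%s' (lower == upper == %g); metric is constant over forest cells.",
        m, b[1]
      ))
    }
    tibble::tibble(metric = m, lower = b[1], upper = b[2])
  })
  attr(params, "clip_percentiles") <- clip_percentiles
  class(params) <- c("ffi_norm_params", class(params))
  params
}

#' Normalize metrics to the unit interval
#'
#' Applies `x_nor = clamp((x - lower) / (upper - lower), 0, 1)` per metric
#' using bounds from [fit_normalization()]. The same bounds must be applied
#' to both epochs so normalized values are comparable across years.
#'
#' @param metrics Metrics table (any subset of epochs).
#' @param params An `ffi_norm_params` object.
#' @return `metrics` with `ed_nor`, `pd_nor`, `mpa_nor` columns added
#'   (`mpa_nor` is `NA` for non-forest cells).
#' @export
normalize_metrics <- function(metrics, params) {
  stopifnot(inherits(params, "ffi_norm_params"))
  b <- function(m, side) params[[side]][params$metric == m]
  dplyr::mutate(metrics,
    ed_nor = clamp01((.data$ed - b("ed", "lower")) / (b("ed", "upper") - b("ed", "lower"))),
    pd_nor = clamp01((.data$pd - b("pd", "lower")) / (b("pd", "upper") - b("pd", "lower"))),
    mpa_nor = clamp01((.data$mpa - b("mpa", "lower")) / (b("mpa", "upper") - b("mpa", "lower")))
  )
}

#' Compose the forest fragmentation index
#'
#' FFI is the weighted average of the normalized metrics, with mean patch
#' area entering inverted (large patches mean LOW fragmentation):
#' `FFI = w_ed * ED_nor + w_pd * PD_nor + w_mpa * (1 - MPA_nor)`.
#' With defaults each component gets weight 1/3. FFI lies in `[0, 1]`;
#' 0 is a fully intact landscape, 1 a maximally fragmented one. Non-forest
#' cells (undefined MPA) get no FFI.
#'
#' @param normalized Output of [normalize_metrics()].
#' @param weights Length-3 non-negative weights for (ED, PD, MPA), summing
#'   to 1 within 1e-9.
#' @return `normalized` with an `ffi` column added.
#' @export
compose_ffi <- function(normalized, weights = c(1, 1, 1) / 3) {
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be 3 non-negative values summing to 1.")
  }
  dplyr::mutate(normalized,
    ffi = weights[1] * .data$ed_nor + weights[2] * .data$pd_nor +
      weights[3] * (1 - .data$mpa_nor)
  )
}

#' Change in index and coverage between two epochs
#'
#' `dFFI = FFI_2 - FFI_1` and `dFC = FC_2 - FC_1`. Negative dFFI means the
#' landscape DEfragmented; positive means fragmentation increased. Both lie
#' in `[-1, 1]`.
#'
#' @param ffi_1,ffi_2 FFI in the earlier / later epoch.
#' @param fc_1,fc_2 Forest coverage fractions in the two epochs.
#' @return Tibble with `d_ffi`, `d_fc`.
#' @export
compute_delta <- function(ffi_1, ffi_2, fc_1, fc_2) {
  tibble::tibble(d_ffi = ffi_2 - ffi_1, d_fc = fc_2 - fc_1)
}

#' Per-cell FFI layers and epoch differences
#'
#' The main indexing stage: fits pooled normalization bounds (unless given),
#' normalizes both epochs with the same bounds, composes FFI per epoch and
#' takes differences. Change columns (`d_*`) are defined only for cells
#' forested in BOTH epochs — the epoch intersection — because the sign
#' classifications downstream need all three metric changes to exist; cells
#' forested in a single epoch keep their static FFI for that epoch with `NA`
#' changes.
#'
#' @param metrics Two-epoch metrics table from [compute_metrics_grid()].
#' @param params Optional pre-fitted [fit_normalization()] bounds.
#' @param clip_percentiles Passed to [fit_normalization()] when `params` is
#'   `NULL`.
#' @param weights Passed to [compose_ffi()].
#' @return Tibble of class `ffi_layers`, one row per cell present in at
#'   least one epoch: `cell_id`, per-epoch `fc_1`, `fc_2`, `ffi_1`, `ffi_2`,
#'   raw metric changes `d_ed`, `d_pd`, `d_mpa`, plus `d_ffi`, `d_fc`. The
#'   fitted params are attached as attribute `norm_params`, epoch labels as
#'   `epochs`.
#' @export
ffi_layers <- function(metrics, params = NULL, clip_percentiles = c(0, 100),
                       weights = c(1, 1, 1) / 3) {
  epochs <- sort(unique(metrics$epoch))
  if (length(epochs) != 2) {
    abort(sprintf("`metrics` must contain exactly 2 epochs, found %d.",
                  length(epochs)))
  }
  if (is.null(params)) params <- fit_normalization(metrics, clip_percentiles)
  scored <- compose_ffi(normalize_metrics(metrics, params), weights)
  scored$which_epoch <- ifelse(scored$epoch == epochs[1], "1", "2")
  wide <- tidyr::pivot_wider(
    dplyr::select(scored, "cell_id", "which_epoch", "ed", "pd", "mpa",
                  "fc", "ffi", "forest"),
    names_from = "which_epoch",
    values_from = c("ed", "pd", "mpa", "fc", "ffi", "forest"),
    names_sep = "_"
  )
  both <- !is.na(wide$forest_1) & !is.na(wide$forest_2) &
    wide$forest_1 & wide$forest_2
  out <- dplyr::mutate(wide,
    d_ed = ifelse(both, .data$ed_2 - .data$ed_1, NA_real_),
    d_pd = ifelse(both, .data$pd_2 - .data$pd_1, NA_real_),
    d_mpa = ifelse(both, .data$mpa_2 - .data$mpa_1, NA_real_),
    d_ffi = ifelse(both, .data$ffi_2 - .data$ffi_1, NA_real_),
    d_fc = ifelse(both, .data$fc_2 - .data$fc_1, NA_real_)
  )
  out <- dplyr::select(out, -"forest_1", -"forest_2")
  attr(out, "norm_params") <- params
  attr(out, "epochs") <- epochs
  attr(out, "weights") <- weights
  class(out) <- c("ffi_layers", class(out))
  out
}

#' Write / read normalization parameters as a YAML sidecar
#'
#' Serializing the fitted bounds lets a later run normalize new data with
#' bit-identical parameters.
#'
#' @param params An `ffi_norm_params` tibble.
#' @param path YAML file path.
#' @return `path` / the restored params.
#' @export
write_norm_params <- function(params, path) {
  stopifnot(inherits(params, "ffi_norm_params"))
  yaml::write_yaml(list(
    clip_percentiles = as.numeric(attr(params, "clip_percentiles")),
    bounds = purrr::pmap(params, function(metric, lower, upper) {
      list(metric = metric, lower = lower, upper = upper)
    })
  ), path)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- purrr::map_dfr(raw$bounds, tibble::as_tibble)
  attr(params, "clip_percentiles") <- as.numeric(raw$clip_percentiles)
  class(params) <- c("ffi_norm_params", class(params))
  params
}
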