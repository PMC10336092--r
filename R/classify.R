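# Categorical classification of fragmentation change.
#
# "up" always means strictly positive change; by the default tie rule an
# exact zero counts as "down", which keeps the classifiers total and
# exhaustive over 8 (modes) and 4 (patterns) categories. Exact zeros are
# measure-zero on real data; `tie = "exclude"` returns NA for them instead.

mode_levels <- function() {
  grid <- tidyr::expand_grid(ed = c("down", "up"), pd = c("down", "up"),
                             mpa = c("down", "up"))
  paste0("ED_", grid$ed, " PD_", grid$pd, " MPA_", grid$mpa)
}

pattern_levels <- function() {
  c("FC_down FFI_down", "FC_down FFI_up", "FC_up FFI_down", "FC_up FFI_up")
}

#' Stage interpretation of the four landscape-dynamic patterns
#'
#' Coverage gain with defragmentation is deep recovery; gain with rising
#' fragmentation is early recovery (new small patches not yet coalesced);
#' loss with falling fragmentation is early degradation (small or irregular
#' patches cleared first); loss with rising fragmentation is deep degradation
#' (loss has reached the large intact patches).
#'
#' @return Tibble `pattern`, `stage`.
#' @export
pattern_stages <- function() {
  tibble::tibble(
    pattern = pattern_levels(),
    stage = c("early degradation", "deep degradation",
              "deep recovery", "early recovery")
  )
}

sign_word <- function(x, tie) {
  out <- ifelse(x > 0, "up", "down")
  if (tie == "exclude") out[x == 0] <- NA_character_
  out
}

#' Classify the fragmentation-process mode of each cell
#'
#' The three metric changes define a sign triple, giving eight modes of the
#' fragmentation process, e.g. `ED_up PD_up MPA_down` (more edge, more
#' patches, smaller patches: classic fragmentation by division) or
#' `ED_down PD_down MPA_up` (patch coalescence/defragmentation).
#'
#' @param d_ed,d_pd,d_mpa Numeric vectors of metric changes (later minus
#'   earlier epoch). Non-finite entries yield `NA`.
#' @param tie `"down"` (default: zero change counts as down) or `"exclude"`
#'   (zero change yields `NA`).
#' @return Factor with the 8 mode levels in fixed code order (codes 0-7
#'   encode the triple as `4*(ED up) + 2*(PD up) + (MPA up)`).
#' @export
classify_mode <- function(d_ed, d_pd, d_mpa, tie = c("down", "exclude")) {
  tie <- match.arg(tie)
  lab <- paste0("ED_", sign_word(d_ed, tie),
                " PD_", sign_word(d_pd, tie),
                " MPA_", sign_word(d_mpa, tie))
  lab[!is.finite(d_ed) | !is.finite(d_pd) | !is.finite(d_mpa)] <- NA
  lab[grepl("NA", lab)] <- NA
  factor(lab, levels = mode_levels())
}

#' Classify the landscape-dynamic pattern of each cell
#'
#' The signs of the coverage change and the index change define four
#' patterns, read as stages of recovery or degradation (see
#' [pattern_stages()]).
#'
#' @param d_fc,d_ffi Numeric vectors of coverage / index changes.
#' @inheritParams classify_mode
#' @return Factor with the 4 pattern levels (codes 0-3 encode
#'   `2*(FC up) + (FFI up)`).
#' @export
classify_pattern <- function(d_fc, d_ffi, tie = c("down", "exclude")) {
  tie <- match.arg(tie)
  lab <- paste0("FC_", sign_word(d_fc, tie), " FFI_", sign_word(d_ffi, tie))
  lab[!is.finite(d_fc) | !is.finite(d_ffi)] <- NA
  lab[grepl("NA", lab)] <- NA
  factor(lab, levels = pattern_levels())
}

#' Add mode, pattern and stage columns to an FFI layers table
#'
#' Data-frame-first wrapper over [classify_mode()] and [classify_pattern()].
#' Also flags cells in the "relatively stable" band `|dFFI| < stable_eps`
#' (descriptive only; stable cells keep their mode/pattern class).
#'
#' @param layers An [ffi_layers()] tibble.
#' @inheritParams classify_mode
#' @param stable_eps Half-width of the stable dFFI band (default 0.005).
#' @return `layers` with `mode`, `pattern`, `stage`, `stable` columns.
#' @export
classify_changes <- function(layers, tie = c("down", "exclude"),
                             stable_eps = 0.005) {
  tie <- match.arg(tie)
  out <- dplyr::mutate(layers,
    mode = classify_mode(.data$d_ed, .data$d_pd, .data$d_mpa, tie = tie),
    pattern = classify_pattern(.data$d_fc, .data$d_ffi, tie = tie),
    stable = is.finite(.data$d_ffi) & abs(.data$d_ffi) < stable_eps
  )
  ps <- pattern_stages()
  out$stage <- ps$stage[match(as.character(out$pattern), ps$pattern)]
  out
}

#' Mode composition within fragmentation strata
#'
#' Area proportions of the eight process modes, computed separately for
#' cells where fragmentation decreased (`dFFI < 0`) and increased
#' (`dFFI > 0`). Cells with exactly zero dFFI belong to neither stratum.
#' All cells have equal area, so proportions are cell-count fractions.
#'
#' @param classified Output of [classify_changes()] (needs `mode`, `d_ffi`).
#' @return Tibble `stratum` (`"dFFI<0"`/`"dFFI>0"`), `mode`, `n_cells`,
#'   `prop` (fractions summing to 1 within each stratum).
#' @export
mode_composition <- function(classified) {
  d <- dplyr::filter(classified, is.finite(.data$d_ffi), .data$d_ffi != 0,
                     !is.na(.data$mode))
  if (nrow(d) == 0) {
    warn("No cells with nonzero dFFI; returning empty composition table.")
    return(tibble::tibble(stratum = character(), mode = factor(levels = mode_levels()),
                          n_cells = integer(), prop = numeric()))
  }
  d$stratum <- ifelse(d$d_ffi < 0, "dFFI<0", "dFFI>0")
  out <- dplyr::count(d, .data$stratum, .data$mode, name = "n_cells",
                      .drop = FALSE)
  out <- dplyr::group_by(out, .data$stratum)
  out <- dplyr::mutate(out, prop = .data$n_cells / sum(.data$n_cells))
  dplyr::ungroup(out)
}

#' Zonal summary of fragmentation layers
#'
#' Aggregates the per-cell layers over categorical zones (climate zones,
#' countries, altitude bands): per-zone FFI means and spreads, mean changes,
#' pattern area percentages and mode shares per dFFI stratum. The `stats`
#' table doubles as the national-scale (mean dFC, mean dFFI) table used for
#' the coverage-change vs fragmentation-change correlation.
#'
#' @param classified Output of [classify_changes()].
#' @param zones Tibble `cell_id`, `zone` (e.g. from [zones_from_map()]).
#' @param cell_area Ground area of one cell in m2 (for absolute areas);
#'   default 1 reports areas in cell counts.
#' @return List of class `zonal_summary`: `stats` (per zone), `pattern_shares`
#'   (zone x pattern area percentages), `mode_shares` (zone x stratum x mode).
#' @export
zonal_summary <- function(classified, zones, cell_area = 1) {
  d <- dplyr::inner_join(classified, zones, by = "cell_id")
  empty <- setdiff(unique(zones$zone), unique(d$zone))
  if (length(empty)) {
    warn(paste("Zones with no cells omitted:", paste(empty, collapse = ", ")))
  }
  stats <- dplyr::summarise(
    dplyr::group_by(d, .data$zone),
    n_cells = dplyr::n(),
    area = dplyr::n() * cell_area,
    mean_ffi_1 = mean(.data$ffi_1, na.rm = TRUE),
    sd_ffi_1 = sd(.data$ffi_1, na.rm = TRUE),
    mean_ffi_2 = mean(.data$ffi_2, na.rm = TRUE),
    sd_ffi_2 = sd(.data$ffi_2, na.rm = TRUE),
    mean_d_ffi = mean(.data$d_ffi, na.rm = TRUE),
    sd_d_ffi = sd(.data$d_ffi, na.rm = TRUE),
    mean_d_fc = mean(.data$d_fc, na.rm = TRUE),
    .groups = "drop"
  )
  pat <- dplyr::filter(d, !is.na(.data$pattern))
  pattern_shares <- dplyr::count(pat, .data$zone, .data$pattern,
                                 name = "n_cells", .drop = FALSE)
  pattern_shares <- dplyr::mutate(
    dplyr::group_by(pattern_shares, .data$zone),
    area = .data$n_cells * cell_area,
    pct = 100 * .data$n_cells / sum(.data$n_cells)
  )
  pattern_shares <- dplyr::ungroup(pattern_shares)
  comp <- dplyr::filter(d, is.finite(.data$d_ffi), .data$d_ffi != 0,
                        !is.na(.data$mode))
  comp$stratum <- ifelse(comp$d_ffi < 0, "dFFI<0", "dFFI>0")
  mode_shares <- dplyr::count(comp, .data$zone, .data$stratum, .data$mode,
                              name = "n_cells", .drop = FALSE)
  mode_shares <- dplyr::mutate(
    dplyr::group_by(mode_shares, .data$zone, .data$stratum),
    pct = 100 * .data$n_cells / sum(.data$n_cells)
  )
  mode_shares <- dplyr::ungroup(mode_shares)
  structure(list(stats = stats, pattern_shares = pattern_shares,
                 mode_shares = mode_shares),
            class = "zonal_summary")
}

#' @export
print.zonal_summary <- function(x, ...) {
  cat("<zonal_summary>\n$stats\n")
  print(x$stats)
  cat("\n$pattern_shares (area %)\n")
  print(tidyr::pivot_wider(
    dplyr::select(x$pattern_shares, "zone", "pattern", "pct"),
    names_from = "pattern", values_from = "pct"
  ))
  invisible(x)
}

#' Metric-change summary for a hotspot selection
#'
#' For a set of cells (a fragmentation hotspot), summarizes each metric per
#' epoch (mean, median, quartiles) and reports the percent change of the
#' mean, `(mean_2 - mean_1) / mean_1 * 100` — the convention used to state
#' e.g. "MPA increased by 73%" for a region.
#'
#' @param metrics Two-epoch table from [compute_metrics_grid()].
#' @param cell_ids Cells belonging to the hotspot.
#' @return Tibble, one row per metric (`ed`, `pd`, `mpa`, `fc`): per-epoch
#'   `mean_*`, `median_*`, `q25_*`, `q75_*` and `pct_change_mean`.
#' @export
hotspot_summary <- function(metrics, cell_ids) {
  if (length(cell_ids) == 0) abort("`cell_ids` must be non-empty.")
  d <- dplyr::filter(metrics, .data$cell_id %in% cell_ids)
  epochs <- sort(unique(d$epoch))
  if (length(epochs) != 2) abort("Hotspot needs both epochs present.")
  long <- tidyr::pivot_longer(
    dplyr::select(d, "cell_id", "epoch", "ed", "pd", "mpa", "fc"),
    cols = c("ed", "pd", "mpa", "fc"),
    names_to = "metric", values_to = "value"
  )
  long$which_epoch <- ifelse(long$epoch == epochs[1], "1", "2")
  s <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$which_epoch),
    mean = mean(.data$value, na.rm = TRUE),
    median = median(.data$value, na.rm = TRUE),
    q25 = unname(quantile(.data$value, 0.25, na.rm = TRUE)),
    q75 = unname(quantile(.data$value, 0.75, na.rm = TRUE)),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(s, names_from = "which_epoch",
                             values_from = c("mean", "median", "q25", "q75"),
                             names_sep = "_")
  dplyr::mutate(wide,
    pct_change_mean = (.data$mean_2 - .data$mean_1) / .data$mean_1 * 100
  )
}
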