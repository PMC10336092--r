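test_that("the eight sign triples map to eight distinct total modes", {
  signs <- tidyr::expand_grid(ed = c(-1, 1), pd = c(-1, 1), mpa = c(-1, 1))
  codes <- classify_mode(signs$ed * 0.1, signs$pd * 0.1, signs$mpa * 0.1)
  expect_equal(length(unique(codes)), 8)
  expect_false(any(is.na(codes)))
  expect_setequal(as.character(codes), levels(codes))
})

test_that("dominant change directions get their canonical mode labels", {
  expect_equal(as.character(classify_mode(-0.1, -0.2, 0.3)),
               "ED_down PD_down MPA_up")
  expect_equal(as.character(classify_mode(0.1, 0.2, -0.3)),
               "ED_up PD_up MPA_down")
})

test_that("zero change is 'down' by default and NA under tie = exclude", {
  expect_equal(as.character(classify_mode(0, 0, 0)),
               "ED_down PD_down MPA_down")
  expect_true(is.na(classify_mode(0, 0.1, -0.1, tie = "exclude")))
  expect_true(is.na(classify_mode(NA, 0.1, -0.1)))
  expect_true(is.na(classify_pattern(0, 0.1, tie = "exclude")))
})

test_that("negating all deltas mirrors every mode component", {
  set.seed(3)
  d <- matrix(runif(300, -1, 1), ncol = 3)
  d <- d[apply(d != 0, 1, all), ]
  a <- as.character(classify_mode(d[, 1], d[, 2], d[, 3]))
  b <- as.character(classify_mode(-d[, 1], -d[, 2], -d[, 3]))
  flip <- function(s) {
    s <- gsub("up", "@", s)
    s <- gsub("down", "up", s)
    gsub("@", "down", s)
  }
  expect_equal(b, flip(a))
})

test_that("the four sign pairs map to four patterns with fixed stages", {
  signs <- tidyr::expand_grid(fc = c(-1, 1), ffi = c(-1, 1))
  codes <- classify_pattern(signs$fc * 0.1, signs$ffi * 0.1)
  expect_equal(length(unique(codes)), 4)

  st <- pattern_stages()
  expect_equal(st$stage[st$pattern == "FC_up FFI_down"], "deep recovery")
  expect_equal(st$stage[st$pattern == "FC_up FFI_up"], "early recovery")
  expect_equal(st$stage[st$pattern == "FC_down FFI_down"], "early degradation")
  expect_equal(st$stage[st$pattern == "FC_down FFI_up"], "deep degradation")

  expect_equal(as.character(classify_pattern(0.02, -0.05)), "FC_up FFI_down")
  expect_equal(as.character(classify_pattern(-0.03, 0.04)), "FC_down FFI_up")
})

toy_classified <- function(modes, d_ffi) {
  tibble::tibble(
    cell_id = seq_along(modes),
    mode = factor(modes, levels = fragdyn:::mode_levels()),
    d_ffi = d_ffi
  )
}

test_that("mode composition sums to one within strata and matches counts", {
  m <- rep("ED_down PD_down MPA_up", 10)
  comp <- mode_composition(toy_classified(m, rep(-0.1, 10)))
  expect_equal(comp$prop[comp$n_cells > 0], 1)

  modes <- c(rep("ED_down PD_down MPA_up", 6), rep("ED_up PD_up MPA_down", 2),
             rep("ED_up PD_down MPA_up", 2))
  comp2 <- mode_composition(toy_classified(modes, rep(-0.2, 10)))
  got <- comp2$prop[match(unique(modes), as.character(comp2$mode))]
  expect_equal(got, c(0.6, 0.2, 0.2))
  expect_equal(sum(comp2$prop[comp2$stratum == "dFFI<0"]), 1)

  # permutation invariance over cells
  perm <- sample(10)
  comp3 <- mode_composition(toy_classified(modes[perm], rep(-0.2, 10)))
  expect_equal(comp3, comp2)

  expect_warning(mode_composition(toy_classified(modes, rep(0, 10))), "nonzero")
})

make_layers <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    cell_id = seq_len(n),
    ffi_1 = runif(n), ffi_2 = runif(n),
    fc_1 = runif(n), fc_2 = runif(n),
    d_ed = runif(n, -1, 1), d_pd = runif(n, -1, 1), d_mpa = runif(n, -1, 1)
  ) |>
    dplyr::mutate(d_ffi = ffi_2 - ffi_1, d_fc = fc_2 - fc_1)
}

test_that("a single zone reproduces the global summary", {
  cl <- classify_changes(make_layers(50))
  zs <- zonal_summary(cl, tibble::tibble(cell_id = 1:50, zone = "all"))
  expect_equal(zs$stats$n_cells, 50)
  expect_equal(zs$stats$mean_d_ffi, mean(cl$d_ffi))
  expect_equal(sum(zs$pattern_shares$pct), 100)
})

test_that("two-zone summaries match hand computation", {
  cl <- classify_changes(tibble::tibble(
    cell_id = 1:6,
    ffi_1 = c(0.2, 0.4, 0.6, 0.1, 0.5, 0.9),
    ffi_2 = c(0.1, 0.5, 0.5, 0.3, 0.4, 0.8),
    fc_1 = rep(0.5, 6), fc_2 = c(0.6, 0.4, 0.7, 0.4, 0.6, 0.9),
    d_ed = c(-1, 1, -1, 1, -1, -1), d_pd = c(-1, 1, -1, 1, -1, -1),
    d_mpa = c(1, -1, 1, -1, 1, 1)
  ) |> dplyr::mutate(d_ffi = ffi_2 - ffi_1, d_fc = fc_2 - fc_1))
  zones <- tibble::tibble(cell_id = 1:6, zone = rep(c("A", "B"), each = 3))
  zs <- zonal_summary(cl, zones, cell_area = 25e6)
  a <- zs$stats[zs$stats$zone == "A", ]
  expect_equal(a$n_cells, 3)
  expect_equal(a$area, 3 * 25e6)
  expect_equal(a$mean_ffi_1, mean(c(0.2, 0.4, 0.6)))
  expect_equal(a$mean_d_ffi, mean(c(-0.1, 0.1, -0.1)))
  expect_equal(a$mean_d_fc, mean(c(0.1, -0.1, 0.2)))
  pa <- zs$pattern_shares[zs$pattern_shares$zone == "A", ]
  expect_equal(sort(pa$pct[pa$n_cells > 0]), sort(c(200 / 3, 100 / 3)))

  expect_warning(
    zonal_summary(cl, tibble::tibble(cell_id = 7:8, zone = "C")),
    "omitted"
  )
})

test_that("hotspot summaries report percent change of the mean", {
  met <- tibble::tibble(
    cell_id = rep(1:10, 2), epoch = rep(c(2000, 2020), each = 10),
    ed = c(rep(10, 10), rep(19, 10)),
    pd = rep(5, 20),
    mpa = c(rep(0.10, 10), rep(0.173, 10)),
    fc = rep(0.5, 20)
  )
  hs <- hotspot_summary(met, cell_ids = 1:10)
  expect_equal(hs$pct_change_mean[hs$metric == "mpa"], 73, tolerance = 1e-9)
  expect_equal(hs$pct_change_mean[hs$metric == "ed"], 90)
  expect_equal(hs$pct_change_mean[hs$metric == "pd"], 0)
  expect_error(hotspot_summary(met, integer(0)), "non-empty")
})
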