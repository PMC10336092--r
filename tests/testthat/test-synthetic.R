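base_spec <- function(...) {
  scenario_spec(nrow = 60, ncol = 60, pixel_size = 30, p = 0.4,
                autocorr = 0.8, seed = 11, ...)
}

whole_map_metrics <- function(map) {
  compute_cell_metrics(map$values, map$pixel_size,
                       length(map$values) * map$pixel_size^2)
}

test_that("initial maps are deterministic under seed and differ across seeds", {
  a <- generate_initial_map(base_spec())
  b <- generate_initial_map(base_spec())
  expect_identical(a$values, b$values)
  spec2 <- scenario_spec(60, 60, p = 0.4, autocorr = 0.8, seed = 12)
  expect_false(identical(a$values, generate_initial_map(spec2)$values))
})

test_that("realized forest proportion hits the requested target", {
  for (p in c(0.1, 0.3, 0.62)) {
    spec <- scenario_spec(80, 80, p = p, autocorr = 0.7, seed = 21)
    m <- generate_initial_map(spec)
    expect_lt(abs(mean(m$values == 1L) - p), 0.01)
  }
})

test_that("higher autocorrelation gives fewer, larger patches at equal cover", {
  stats <- purrr::map_dfr(1:15, function(s) {
    purrr::map_dfr(c(0.1, 0.9), function(ac) {
      spec <- scenario_spec(60, 60, p = 0.35, autocorr = ac, seed = 100 + s)
      met <- whole_map_metrics(generate_initial_map(spec))
      tibble::tibble(autocorr = ac, n_patches = met$n_patches, mpa = met$mpa)
    })
  })
  lo <- dplyr::filter(stats, autocorr == 0.1)
  hi <- dplyr::filter(stats, autocorr == 0.9)
  expect_lt(mean(hi$n_patches), mean(lo$n_patches))
  expect_gt(mean(hi$mpa), mean(lo$mpa))
})

test_that("scenario specs validate their fields", {
  expect_error(scenario_spec(10, 10, p = 1.2), "between 0 and 1")
  expect_error(scenario_spec(10, 10, autocorr = 1), "\\[0, 1\\)")
  expect_error(base_spec(schedule = list(list(operator = "bulldoze",
                                              intensity = 0.5))),
               "operator")
  expect_error(base_spec(schedule = list(list(operator = "infill",
                                              intensity = 2))),
               "intensity")
  expect_error(base_spec(schedule = list(list(operator = "infill",
                                              intensity = 0.5,
                                              region = c(1, 10)))),
               "region")
})

test_that("zero intensity is the identity and unknown operators fail", {
  m <- generate_initial_map(base_spec())
  expect_identical(apply_operator(m, "edge_erosion", 0)$values, m$values)
  expect_error(apply_operator(m, "clearcut", 0.5), "Unknown operator")
})

test_that("attrition removes exactly the smallest patches", {
  v <- matrix(0L, 20, 20)
  v[1:6, 1:6] <- 1L      # 36 px
  v[10:13, 10:13] <- 1L  # 16 px
  v[1, 19:20] <- 1L      # 2 px
  v[20, 1] <- 1L         # 1 px
  v[16:17, 3:4] <- 1L    # 4 px
  m <- forest_map(v, pixel_size = 30)
  before <- label_patches(m$values)
  expect_equal(before$n_patches, 5)
  out <- apply_operator(m, "attrition", intensity = 0.4, seed = 1)
  after <- label_patches(out$values)
  expect_equal(after$n_patches, 3)
  expect_setequal(after$patch_areas_px, c(36L, 16L, 4L))
})

test_that("edge erosion shrinks forest without creating detached patches", {
  set.seed(2)
  for (s in 1:5) {
    m <- generate_initial_map(scenario_spec(50, 50, p = 0.45, autocorr = 0.8,
                                            seed = 200 + s))
    out <- apply_operator(m, "edge_erosion", 0.5, seed = s)
    expect_lt(forest_pixels(out), forest_pixels(m))
    # every surviving patch is contained in one original patch
    lab0 <- label_patches(m$values)$labels
    lab1 <- label_patches(out$values)
    for (k in seq_len(lab1$n_patches)) {
      parents <- unique(lab0[lab1$labels == k])
      expect_length(parents, 1)
      expect_gt(parents, 0)
    }
  }
})

test_that("operators move coverage and metrics in their expected directions", {
  truth <- fragdyn:::operator_truth()
  n_rep <- 12
  for (op in truth$operator) {
    want <- truth[truth$operator == op, ]
    ok_fc <- 0
    ok_metrics <- 0
    n_metrics <- 0
    for (s in seq_len(n_rep)) {
      spec <- scenario_spec(60, 60, p = 0.45, autocorr = 0.85, seed = 300 + s)
      m1 <- generate_initial_map(spec)
      m2 <- apply_operator(m1, op, intensity = 0.5, seed = 400 + s)
      a <- whole_map_metrics(m1)
      b <- whole_map_metrics(m2)
      if (!is.na(want$d_fc) && sign(b$fc - a$fc) == want$d_fc) ok_fc <- ok_fc + 1
      for (mcol in c("d_ed", "d_pd", "d_mpa")) {
        if (is.na(want[[mcol]])) next
        raw <- switch(mcol, d_ed = b$ed - a$ed, d_pd = b$pd - a$pd,
                      d_mpa = b$mpa - a$mpa)
        n_metrics <- n_metrics + 1
        if (sign(raw) == want[[mcol]]) ok_metrics <- ok_metrics + 1
      }
    }
    expect_gte(ok_fc, n_rep - 1) # coverage direction is near-deterministic
    if (n_metrics > 0) expect_gte(ok_metrics / n_metrics, 0.9)
  }
})

test_that("an empty schedule reproduces the first epoch unchanged", {
  sc <- generate_scenario(base_spec())
  expect_identical(sc$map_1$values, sc$map_2$values)
  expect_equal(sc$map_1$epoch, 2000)
  expect_equal(sc$map_2$epoch, 2020)
  expect_equal(nrow(sc$truth), 0)
})

test_that("scenario truth records operators with their expected signs", {
  spec <- base_spec(schedule = list(
    list(operator = "dissection", intensity = 0.5, region = c(1L, 60L, 1L, 30L)),
    list(operator = "infill", intensity = 0.5, region = c(1L, 60L, 31L, 60L))
  ))
  sc <- generate_scenario(spec)
  expect_equal(sc$truth$operator, c("dissection", "infill"))
  expect_equal(sc$truth$d_ffi, c(1, -1))
  expect_equal(sc$truth$d_ed, c(1, -1))
  # operators acted only inside their regions
  expect_false(identical(sc$map_1$values, sc$map_2$values))
})

test_that("driver fields are reproducible and carry their truth", {
  beta <- c(0.3, -0.2, 0, 0, 0, 0, 0.4)
  a <- generate_driver_fields(20, 20, beta, seed = 77)
  b <- generate_driver_fields(20, 20, beta, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(unname(attr(a, "truth")), beta)
  expect_true(all(vapply(a[driver_names()], function(x)
    min(x) >= 0 && max(x) <= 1, logical(1))))
  expect_error(generate_driver_fields(10, 10, c(0.1, 0.2)), "length 7")
})

test_that("driver tables built from rasters take means, changes and fire counts", {
  fm <- forest_map(matrix(1L, 4, 4), pixel_size = 50)
  g <- build_grid(fm, cell_size = 100)
  crop1 <- matrix(0.2, 4, 4)
  crop2 <- matrix(0.4, 4, 4)
  fire <- matrix(rep(c(0, 1), each = 8), 4, 4)
  d <- build_driver_table(g, cropland = list(crop1, crop2), fire = fire)
  expect_equal(d$cropland_mean, rep(0.3, 4))
  expect_equal(d$cropland_change, rep(0.2, 4))
  expect_equal(d$fire_freq, c(0, 1, 0, 1))
})
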