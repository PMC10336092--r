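test_that("patch labeling handles the canonical small cases", {
  expect_equal(label_patches(matrix(0L, 5, 5))$n_patches, 0)
  expect_error(label_patches(matrix(integer(0), 0, 0)), "non-empty")

  diag2 <- matrix(0L, 3, 3)
  diag2[1, 1] <- 1L
  diag2[2, 2] <- 1L
  expect_equal(label_patches(diag2, connectivity = 8)$n_patches, 1)
  expect_equal(label_patches(diag2, connectivity = 4)$n_patches, 2)

  w <- matrix(0L, 5, 5)
  w[2:3, 2:3] <- 1L
  w[5, 5] <- 1L
  lp <- label_patches(w)
  expect_equal(lp$n_patches, 2)
  expect_setequal(lp$patch_areas_px, c(4L, 1L))
})

test_that("labels are assigned row-major from each patch's first pixel", {
  w <- matrix(0L, 4, 4)
  w[4, 1] <- 1L # later in row-major scan
  w[1, 4] <- 1L # first row, so first label
  lp <- label_patches(w)
  expect_equal(lp$labels[1, 4], 1L)
  expect_equal(lp$labels[4, 1], 2L)
})

test_that("nodata is background for labeling but area bookkeeping holds", {
  w <- matrix(1L, 3, 3)
  w[2, 2] <- NA
  lp <- label_patches(w)
  expect_equal(sum(lp$patch_areas_px), sum(w == 1L, na.rm = TRUE))
  expect_equal(lp$n_patches, 1)
})

test_that("edge length matches direct adjacency reasoning", {
  full <- matrix(1L, 10, 10)
  expect_equal(edge_length(full, 10), 0)

  w <- matrix(0L, 10, 10)
  w[5:6, 5:6] <- 1L
  expect_equal(edge_length(w, 10), 80) # 8 adjacencies x 10 m

  corner <- matrix(0L, 5, 5)
  corner[1, 1] <- 1L
  expect_equal(edge_length(corner, 10), 20)
  expect_equal(edge_length(corner, 10, count_boundary = TRUE), 40)

  # forest-nodata adjacency is not edge
  wn <- matrix(0L, 3, 3)
  wn[2, 2] <- 1L
  wn[2, 3] <- NA
  expect_equal(edge_length(wn, 10), 30)
})

test_that("single-cell metrics follow the defining equations", {
  w <- matrix(0L, 10, 10)
  w[5:6, 5:6] <- 1L
  row <- compute_cell_metrics(w, pixel_size = 10, cell_area = 1e4)
  expect_equal(row$ed, 80)
  expect_equal(row$pd, 100)
  expect_equal(row$mpa, 0.04)
  expect_equal(row$fc, 0.04)

  full <- compute_cell_metrics(matrix(1L, 10, 10), 10, 1e4)
  expect_equal(full$ed, 0)
  expect_equal(full$pd, 100)
  expect_equal(full$mpa, 1)
  expect_equal(full$fc, 1)

  none <- compute_cell_metrics(matrix(0L, 10, 10), 10, 1e4)
  expect_equal(none$ed, 0)
  expect_equal(none$pd, 0)
  expect_true(is.na(none$mpa))
  expect_equal(none$fc, 0)
  expect_false(none$forest)
})

test_that("metrics agree exactly with the brute-force oracle on random windows", {
  set.seed(101)
  for (i in 1:60) {
    conn <- if (i %% 2 == 0) 8 else 4
    w <- random_window(sample(5:30, 1), sample(5:30, 1), runif(1, 0.2, 0.8))
    got <- compute_cell_metrics(w, pixel_size = 10,
                                cell_area = length(w) * 100,
                                connectivity = conn)
    want <- oracle_metrics(w, 10, length(w) * 100, conn)
    expect_identical(got$ed, want$ed)
    expect_identical(got$pd, want$pd)
    expect_equal(got$mpa, want$mpa)
    expect_identical(got$fc, want$fc)
  }
})

test_that("removing an isolated pixel decreases PD and edge, never raises ED", {
  set.seed(7)
  tried <- 0
  for (i in 1:50) {
    w <- random_window(15, 15, 0.3)
    isolated <- which(w == 1L & neighbour_count_ref(w) == 0L)
    if (!length(isolated)) next
    tried <- tried + 1
    before <- compute_cell_metrics(w, 10, 2.25e4)
    w2 <- w
    w2[isolated[1]] <- 0L
    after <- compute_cell_metrics(w2, 10, 2.25e4)
    expect_lt(after$pd, before$pd)
    expect_lt(after$e_total, before$e_total)
    expect_lte(after$ed, before$ed)
  }
  expect_gt(tried, 10)
})

test_that("metrics scale correctly with pixel size", {
  set.seed(11)
  w <- random_window(20, 20, 0.4)
  a <- compute_cell_metrics(w, pixel_size = 10, cell_area = 400 * 100)
  b <- compute_cell_metrics(w, pixel_size = 20, cell_area = 400 * 400)
  expect_equal(b$e_total, 2 * a$e_total)
  expect_equal(b$ed, a$ed / 2)
  expect_equal(b$pd, a$pd / 4)
  expect_equal(b$mpa, a$mpa * 4)
})

test_that("MPA times patch count equals total forest area exactly", {
  set.seed(13)
  for (i in 1:20) {
    w <- random_window(25, 25, runif(1, 0.1, 0.9))
    r <- compute_cell_metrics(w, 30, 625 * 900)
    if (r$n_patches > 0) {
      expect_equal(r$mpa * r$n_patches, r$forest_pixels * 900 / 1e4)
    }
  }
})

test_that("gridded metrics cover cells independently and deterministically", {
  v <- matrix(0L, 20, 20)
  v[1:10, 1:10] <- 1L # one fully forested cell
  m <- forest_map(v, pixel_size = 10, epoch = 2000)
  g <- build_grid(m, cell_size = 100)
  tab <- compute_metrics_grid(m, g)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$forest), 1)
  expect_equal(tab$fc[tab$forest], 1)
  expect_equal(tab$epoch, rep(2000, 4))

  # determinism: identical inputs give identical tables
  expect_identical(tab, compute_metrics_grid(m, g))

  other <- forest_map(matrix(1L, 20, 20), pixel_size = 25)
  expect_error(compute_metrics_grid(other, g), "pixel size")
})

test_that("cells dominated by nodata are dropped", {
  v <- matrix(1L, 20, 20)
  v[1:10, 1:10] <- NA # cell 1 fully nodata
  v[1, 11] <- NA      # cell 2 only 1% nodata
  m <- forest_map(v, pixel_size = 10)
  g <- build_grid(m, cell_size = 100)
  tab <- compute_metrics_grid(m, g)
  expect_equal(nrow(tab), 3)
  expect_false(1 %in% tab$cell_id)
  # nodata not counted as forest; landscape area stays nominal
  expect_equal(tab$fc[tab$cell_id == 2], 99 / 100)
})
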