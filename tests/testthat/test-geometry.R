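test_that("the foveal pit is located at its true position, centred or offset", {
  pv <- pit_phantom()
  vs <- pv$truth$spec$voxel_size
  fov <- locate_fovea(pv$truth$surfaces, vs)
  expect_lte(abs(fov$x - pv$truth$fovea_index[["x"]]), 1)
  expect_lte(abs(fov$y - pv$truth$fovea_index[["y"]]), 1)

  off <- generate_volume(pit_spec(fovea = list(offset_mm = c(0.5, 0),
                                               pit_depth_um = 90,
                                               pit_radius_mm = 0.6)))
  fov2 <- locate_fovea(off$truth$surfaces, vs)
  expect_lte(abs(fov2$x - off$truth$fovea_index[["x"]]), 1)
})

test_that("fovea ties break towards the scan centre, then scan order", {
  nx <- 11; ny <- 5
  depths <- array(0, dim = c(nx, ny, 11))
  dist <- matrix(10, nx, ny)
  dist[3, 3] <- 2; dist[9, 3] <- 2  # symmetric about centre x = 6
  depths[, , 2] <- dist
  for (k in 3:11) depths[, , k] <- depths[, , k - 1] + 5
  s <- surface_set(depths)
  fov <- locate_fovea(s, c(100, 100, 2.3), central_fraction = 1)
  expect_identical(fov$x, 3L)  # equidistant: first in scan order wins
  expect_identical(fov$y, 3L)
})

test_that("a pit-free surface set triggers the manual-override error", {
  pv <- planar_phantom()
  expect_error(locate_fovea(pv$truth$surfaces, pv$truth$spec$voxel_size),
               "manual")
})

test_that("quadrants tile the square in near-equal parts", {
  grid <- make_quadrant_grid(list(x = 64, y = 32), c(128, 64),
                             c(46.88, 93.75, 2.3), "OD")
  n <- table(factor(grid$labels, levels = c("SN", "IN", "ST", "IT")))
  inside <- sum(n)
  expect_true(all(abs(n - inside / 4) <= max(dim(grid$labels))))
  # disjoint + tiling is structural: every inside A-line has exactly 1 label
  expect_true(all(grid$labels %in% c("SN", "IN", "ST", "IT", "outside")))
})

test_that("the 5 mm square spans the printed number of B-scan columns", {
  # full-resolution geometry: 23.44 um slow-axis pitch
  grid <- make_quadrant_grid(list(x = 256, y = 128), c(512, 256),
                             c(11.72, 23.44, 2.3), "OD")
  ys <- which(apply(grid$labels != "outside", 2, any))
  expect_identical(length(ys), as.integer(round(5000 / 23.44)))
  xs <- which(apply(grid$labels != "outside", 1, any))
  expect_identical(length(xs), as.integer(round(5000 / 11.72)))
})

test_that("x-mirroring plus laterality flip preserves labels and values", {
  nx <- 40; ny <- 24
  fov <- list(x = 17, y = 13)
  g_od <- make_quadrant_grid(fov, c(nx, ny), c(150, 250, 2.3), "OD")
  fov_m <- list(x = nx + 1 - fov$x, y = fov$y)
  g_os <- make_quadrant_grid(fov_m, c(nx, ny), c(150, 250, 2.3), "OS")
  # anatomical preservation: the label at the mirrored position is unchanged
  expect_identical(g_os$labels[nx:1, ], g_od$labels)
  # hence all five region values are invariant for a mirrored map
  set.seed(5)
  map <- matrix(rnorm(nx * ny), nx, ny)
  rv_od <- region_values(map, g_od)
  rv_os <- region_values(map[nx:1, ], g_os)
  expect_identical(rv_od$values, rv_os$values)
  expect_identical(rv_od$n, rv_os$n)
})

test_that("region aggregation: constants, indicators, weighted-mean identity", {
  grid <- make_quadrant_grid(list(x = 33, y = 17), c(64, 32),
                             c(93.75, 187.5, 2.3), "OD")
  cmap <- matrix(3.5, 64, 32)
  rv <- region_values(cmap, grid)
  expect_true(all(rv$values == 3.5))

  ind <- matrix(0, 64, 32); ind[grid$labels == "SN"] <- 1
  rvi <- region_values(ind, grid)
  expect_identical(unname(rvi$values[c("SN", "IN", "ST", "IT")]), c(1, 0, 0, 0))
  expect_equal(rvi$values[["Average"]], rvi$n[["SN"]] / rvi$n[["Average"]])

  set.seed(9)
  rmap <- matrix(rnorm(64 * 32), 64, 32)
  rvr <- region_values(rmap, grid)
  w <- rvr$n[c("SN", "IN", "ST", "IT")]
  expect_equal(rvr$values[["Average"]],
               sum(rvr$values[c("SN", "IN", "ST", "IT")] * w) / sum(w))
})

test_that("masked-out quadrants report NA, never zero", {
  grid <- make_quadrant_grid(list(x = 17, y = 9), c(32, 16),
                             c(187.5, 375, 2.3), "OD")
  map <- matrix(1, 32, 16)
  mask <- matrix(TRUE, 32, 16); mask[grid$labels == "IT"] <- FALSE
  rv <- region_values(map, grid, mask)
  expect_true(is.na(rv$values[["IT"]]))
  expect_identical(rv$n[["IT"]], 0L)
  expect_gt(rv$n_excluded, 0)
})

test_that("fovea outside the scan is rejected", {
  expect_error(make_quadrant_grid(list(x = 200, y = 10), c(64, 32),
                                  c(93.75, 187.5, 2.3), "OD"),
               "outside the scan")
})
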