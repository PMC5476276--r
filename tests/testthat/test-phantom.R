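test_that("zero attenuation and no speckle give flat layers at incident x backscatter", {
  mu0 <- stats::setNames(rep(0, 10), oct_layers())
  sp <- planar_spec(attenuation = mu0,
                    vitreous = list(mu = 0, backscatter = 0.02),
                    sub_rpe = list(mu = 0, backscatter = 0.30),
                    grid_shape = c(32, 8, 256))
  pv <- generate_volume(sp)
  su <- unclass(pv$truth$surfaces)
  for (l in c("RNFL", "ONL", "RPE")) {
    lb <- layer_bounds(l)
    lo <- ceiling(su[1, 1, lb[1]]); hi <- ceiling(su[1, 1, lb[2]])
    vox <- pv$volume$intensity[1, 1, (lo + 1):hi]
    expect_true(all(abs(vox - sp$incident * sp$backscatter[[l]]) <= 0.5),
                label = paste("flat intensity in", l))
  }
})

test_that("generated grid matches the spec shape and the 16-bit contract", {
  pv <- default_phantom()
  expect_identical(dim(pv$volume$intensity), c(128L, 64L, 256L))
  expect_true(all(pv$volume$intensity >= 0 & pv$volume$intensity <= 65535))
  expect_true(all(pv$volume$intensity == round(pv$volume$intensity)))
})

test_that("slab mean intensity matches the analytic Beer-Lambert depth integral", {
  # layer of interest: ONL with mu = 5/mm; oracle computed from first
  # principles in this test, independent of the generator's internals
  mu <- default_attenuation(); mu["ONL"] <- 5
  sp <- planar_spec(attenuation = mu, grid_shape = c(16, 4, 256))
  pv <- generate_volume(sp)
  su <- unclass(pv$truth$surfaces)
  zres_mm <- sp$voxel_size[3] / 1000
  lo <- ceiling(su[1, 1, "OPL_ONL"]); hi <- ceiling(su[1, 1, "ONL_ELM"])
  measured <- mean(pv$volume$intensity[1, 1, (lo + 1):hi])
  # analytic: attenuation above the slab (voxelized path, consistent with the
  # stated half-open slab model), then the closed-form within-slab integral
  bvec <- c(sp$vitreous$backscatter, unname(sp$backscatter), sp$sub_rpe$backscatter)
  muvec <- c(sp$vitreous$mu, unname(sp$attenuation), sp$sub_rpe$mu)
  cuts <- ceiling(su[1, 1, ])
  region_of <- function(z) sum(z >= cuts)  # 0-based voxel -> region index
  A <- sum(vapply(0:(lo - 1), function(z) muvec[region_of(z) + 1], 1))
  d_mm <- (hi - lo) * zres_mm
  m <- 5
  analytic <- sp$incident * sp$backscatter[["ONL"]] *
    exp(-2 * zres_mm * A) * (1 - exp(-2 * m * d_mm)) / (2 * m * d_mm)
  expect_lt(abs(measured - analytic) / analytic, 0.005)
})

test_that("noise-free intensity is non-increasing with depth inside an attenuating layer", {
  pv <- planar_phantom()
  su <- unclass(pv$truth$surfaces)
  lo <- ceiling(su[5, 3, "OPL_ONL"]); hi <- ceiling(su[5, 3, "ONL_ELM"])
  prof <- pv$volume$intensity[5, 3, (lo + 1):hi]
  expect_true(all(diff(prof) <= 0))
})

test_that("speckle is unit-mean: volume mean matches the noise-free expectation", {
  sp_nf <- planar_spec(seed = 2)
  sp_sp <- planar_spec(seed = 2)
  sp_sp$speckle_shape <- 28
  nf <- generate_volume(sp_nf)$volume$intensity
  spk <- generate_volume(sp_sp)$volume$intensity
  expect_lt(abs(mean(spk) - mean(nf)) / mean(nf), 0.005)
})

test_that("truth surfaces never cross and agree with the thickness maps", {
  pv <- default_phantom()
  su <- unclass(pv$truth$surfaces)
  expect_true(all(su[, , -1] - su[, , -11] >= -1e-9))
  zres <- pv$truth$spec$voxel_size[3]
  for (i in seq_along(oct_layers())) {
    d <- (su[, , i + 1] - su[, , i]) * zres
    expect_equal(d, pv$truth$thickness_maps[[i]], tolerance = 1e-12)
  }
})

test_that("volume generation is deterministic and rejects impossible grids", {
  a <- generate_volume(phantom_spec(grid_shape = c(16, 4, 256), seed = 9))
  b <- generate_volume(phantom_spec(grid_shape = c(16, 4, 256), seed = 9))
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(unclass(a$truth$surfaces), unclass(b$truth$surfaces))
  expect_error(generate_volume(phantom_spec(grid_shape = c(16, 4, 64))),
               "grid too small")
})

test_that("null cohorts are exchangeable and designed deltas are realized", {
  # null: no group effects -> group means of true nasal mRNFL thickness agree
  null_cs <- cohort_spec(n_patient = 15, n_control = 15,
                         thickness_deltas = list(),
                         mu_deltas = numeric(0), seed = 21)
  co <- generate_cohort(null_cs)
  nasal_mean <- function(s) {
    tr <- s$truth
    vs <- tr$spec$voxel_size
    grid <- make_quadrant_grid(list(x = round(tr$fovea_index[["x"]]),
                                    y = round(tr$fovea_index[["y"]])),
                               dim(tr$surfaces)[1:2], vs, s$meta$laterality)
    m <- thickness_map(tr$surfaces, "mRNFL", vs)
    lab <- grid$labels
    mean(m[lab %in% c("SN", "IN")])
  }
  v <- vapply(co, nasal_mean, numeric(1))
  g <- vapply(co, function(s) s$meta$group, character(1))
  dnull <- mean(v[g == "patient"]) - mean(v[g == "control"])
  se <- sqrt(stats::var(v[g == "patient"]) / 15 +
               stats::var(v[g == "control"]) / 15)
  expect_lt(abs(dnull), 3 * se)

  # designed effect: -5 um nasal mRNFL, between-subject SD 3
  eff_cs <- cohort_spec(n_patient = 20, n_control = 20,
                        thickness_deltas = list(
                          RNFL = c(SN = -5, IN = -5, ST = 0, IT = 0)),
                        mu_deltas = numeric(0),
                        thickness_sd = c(RNFL = 3, GCL = 2, IPL = 2, INL = 2,
                                         OPL = 2, ONL = 4, ELM = 1, ISOS = 1.5,
                                         OS = 1.5, RPE = 1.5),
                        seed = 22)
  co2 <- generate_cohort(eff_cs)
  v2 <- vapply(co2, nasal_mean, numeric(1))
  g2 <- vapply(co2, function(s) s$meta$group, character(1))
  deff <- mean(v2[g2 == "patient"]) - mean(v2[g2 == "control"])
  se2 <- sqrt(stats::var(v2[g2 == "patient"]) / 20 +
                stats::var(v2[g2 == "control"]) / 20)
  expect_lt(abs(deff - (-5)), 2 * se2)
})

test_that("cohort generation is bit-reproducible for a fixed seed", {
  cs <- cohort_spec(n_patient = 3, n_control = 3, seed = 4)
  a <- generate_cohort(cs, volumes = TRUE)
  b <- generate_cohort(cs, volumes = TRUE)
  expect_identical(lapply(a, function(s) s$volume$intensity),
                   lapply(b, function(s) s$volume$intensity))
  expect_identical(cohort_meta(a), cohort_meta(b))
})

test_that("closed-form layer signals match integrating a rendered volume", {
  pv <- planar_phantom()
  sig <- expected_layer_signals(pv$truth$surfaces, pv$truth$spec,
                                pv$truth$spec$voxel_size)
  zres_mm <- pv$truth$spec$voxel_size[3] / 1000
  for (l in c("RNFL", "ONL", "RPE")) {
    vox <- layer_signal(pv$volume, pv$truth$surfaces, l)
    # voxel sums approximate the continuous integral / dz
    rel <- abs(vox$sum * zres_mm - sig$integral[, , l]) / sig$integral[, , l]
    expect_lt(max(rel), 0.05)
  }
})
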