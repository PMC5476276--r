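# Layered Beer-Lambert speckle phantom: single volumes and two-group cohorts
# with known ground truth, emulating the statistical structure the
# quantification pipeline assumes.

#' Phantom volume specification
#'
#' Describes a synthetic SD-OCT volume: grid geometry, ten per-layer nominal
#' thicknesses with smooth spatial variation, a foveal pit thinning the inner
#' layers (RNFL/GCL/IPL) towards zero at its centre, parabolic axial bowing,
#' per-layer attenuation and backscatter, multiplicative Gamma speckle with
#' unit mean, and a device-style quality score derived from the speckle shape.
#'
#' The noise-free signal model is two-way Beer-Lambert: the expected intensity
#' at depth z inside layer l is
#' `incident * backscatter_l * exp(-2 * integral of mu over the path)`,
#' with `mu` in 1/mm and path lengths in mm. Speckle multiplies each voxel by
#' an independent Gamma(shape, rate = shape) draw, so the expected intensity
#' is unchanged. The default transverse pitch scales with the grid so the
#' field of view stays 6 x 6 mm (the full 512 x 256 grid gives an
#' 11.72 x 23.44 um pitch; the desk-scale default 128 x 64 x 256 grid is
#' sized for routine testing).
#'
#' @param grid_shape integer length-3 `(n_x, n_y, n_z)` voxels.
#' @param voxel_size numeric length-3 voxel pitch in um; default
#'   `c(6000/n_x, 6000/n_y, 2.3)`.
#' @param layer_thickness named numeric, nominal thickness (um) of the ten
#'   layers of [oct_layers()].
#' @param thickness_wobble amplitude of the smooth multiplicative spatial
#'   variation applied to each layer's thickness field.
#' @param fovea list: `offset_mm` (length-2 transverse offset of the pit from
#'   scan centre), `pit_depth_um` (total inner-layer thinning at the centre),
#'   `pit_radius_mm` (Gaussian radius of the pit).
#' @param curvature_um amplitude of the parabolic axial bowing (applied
#'   equally to all surfaces; 0 gives planar layers).
#' @param attenuation named numeric, per-layer `mu` in 1/mm.
#' @param backscatter named numeric in `(0, 1]`, per-layer backscatter
#'   fraction (RPE highest, vitreous lowest).
#' @param vitreous,sub_rpe lists with `mu` and `backscatter` for the regions
#'   above the ILM and below Bruch's membrane (the sub-RPE residual signal is
#'   rapidly attenuated so the bottom surface stays unambiguous).
#' @param vitreous_depth_um nominal depth of the ILM below the scan top.
#' @param incident incident intensity in AU on the 16-bit scale.
#' @param speckle_shape Gamma shape parameter of the multiplicative speckle
#'   (larger = cleaner); `Inf` disables speckle.
#' @param quality_shape_ref half-saturation constant of the quality mapping
#'   `quality = 100 * shape / (shape + quality_shape_ref)`.
#' @param laterality `"OD"` or `"OS"`.
#' @param subject_id identifier attached to the generated volume.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(128L, 64L, 256L),
                         voxel_size = NULL,
                         layer_thickness = NULL,
                         thickness_wobble = 0.04,
                         fovea = list(offset_mm = c(0, 0),
                                      pit_depth_um = 90,
                                      pit_radius_mm = 0.6),
                         curvature_um = 30,
                         attenuation = NULL,
                         backscatter = NULL,
                         vitreous = list(mu = 0.05, backscatter = 0.02),
                         sub_rpe = list(mu = 40, backscatter = 0.30),
                         vitreous_depth_um = 150,
                         incident = 60000,
                         speckle_shape = 28,
                         quality_shape_ref = 12,
                         laterality = "OD",
                         subject_id = "phantom",
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  if (is.null(voxel_size))
    voxel_size <- c(6000 / grid_shape[1], 6000 / grid_shape[2], 2.3)
  if (is.null(layer_thickness)) layer_thickness <- default_layer_thickness()
  if (is.null(attenuation)) attenuation <- default_attenuation()
  if (is.null(backscatter)) backscatter <- default_backscatter()
  ln <- oct_layers()
  stopifnot(all(ln %in% names(layer_thickness)),
            all(ln %in% names(attenuation)),
            all(ln %in% names(backscatter)))
  if (any(layer_thickness < 0)) stop("layer thicknesses must be >= 0")
  if (any(attenuation < 0)) stop("attenuation values must be >= 0")
  if (any(backscatter <= 0 | backscatter > 1))
    stop("backscatter fractions must lie in (0, 1]")
  structure(list(
    grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
    layer_thickness = layer_thickness[ln],
    thickness_wobble = thickness_wobble,
    fovea = fovea, curvature_um = curvature_um,
    attenuation = attenuation[ln], backscatter = backscatter[ln],
    vitreous = vitreous, sub_rpe = sub_rpe,
    vitreous_depth_um = vitreous_depth_um,
    incident = incident, speckle_shape = speckle_shape,
    quality_shape_ref = quality_shape_ref,
    laterality = laterality, subject_id = subject_id,
    seed = as.integer(seed)), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_layer_thickness <- function() {
  c(RNFL = 32, GCL = 33, IPL = 32, INL = 30, OPL = 25,
    ONL = 65, ELM = 8, ISOS = 20, OS = 18, RPE = 22)
}

#' @rdname phantom_spec
#' @export
default_attenuation <- function() {
  c(RNFL = 7.4, GCL = 5.6, IPL = 5.6, INL = 4.0, OPL = 4.2,
    ONL = 1.6, ELM = 3.0, ISOS = 6.0, OS = 6.0, RPE = 15.0)
}

#' @rdname phantom_spec
#' @export
default_backscatter <- function() {
  c(RNFL = 0.45, GCL = 0.28, IPL = 0.36, INL = 0.22, OPL = 0.34,
    ONL = 0.14, ELM = 0.40, ISOS = 0.60, OS = 0.48, RPE = 0.90)
}

.quality_from_shape <- function(shape, ref = 12) {
  if (!is.finite(shape)) return(99)
  100 * shape / (shape + ref)
}

.shape_from_quality <- function(q, ref = 12) ref * q / (100 - q)

# ---- truth construction ----------------------------------------------------

# smooth multiplicative spatial variation field, deterministic given phases
.wobble_field <- function(nx, ny, amp, phases) {
  if (amp <= 0) return(matrix(1, nx, ny))
  gx <- sin(2 * pi * (seq_len(nx) / nx) + phases[1])
  gy <- sin(2 * pi * (seq_len(ny) / ny) + phases[2])
  1 + amp * outer(gx, gy)
}

# per-layer thickness maps (um) with wobble, fovea pit and optional extra
# additive offsets; pit thins RNFL/GCL/IPL with a Gaussian radial profile
.thickness_maps <- function(spec, offsets = NULL) {
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  ln <- oct_layers()
  fx <- (nx + 1) / 2 + spec$fovea$offset_mm[1] * 1000 / spec$voxel_size[1]
  fy <- (ny + 1) / 2 + spec$fovea$offset_mm[2] * 1000 / spec$voxel_size[2]
  rx <- (seq_len(nx) - fx) * spec$voxel_size[1] / 1000
  ry <- (seq_len(ny) - fy) * spec$voxel_size[2] / 1000
  r2 <- outer(rx^2, ry^2, "+")
  pit <- exp(-r2 / spec$fovea$pit_radius_mm^2)
  inner <- c("RNFL", "GCL", "IPL")
  inner_total <- sum(spec$layer_thickness[inner])
  pit_frac <- min(0.98, spec$fovea$pit_depth_um / inner_total)
  maps <- vector("list", length(ln)); names(maps) <- ln
  for (i in seq_along(ln)) {
    l <- ln[i]
    f <- .wobble_field(nx, ny, spec$thickness_wobble,
                       phases = c(0.7, 1.3) * i + spec$seed %% 7)
    m <- spec$layer_thickness[[l]] * f
    if (l %in% inner) m <- m * (1 - pit_frac * pit)
    if (!is.null(offsets) && !is.null(offsets[[l]])) m <- m + offsets[[l]]
    m[m < spec$voxel_size[3]] <- spec$voxel_size[3]  # clamp at one voxel
    maps[[l]] <- m
  }
  attr(maps, "fovea_index") <- c(x = fx, y = fy)
  maps
}

# stack thickness maps into a surface set (0-based fractional voxel depths)
.surfaces_from_thickness <- function(spec, maps) {
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  zres <- spec$voxel_size[3]
  cx <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  cy <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  bowl <- spec$curvature_um / zres * outer(cx^2, cy^2, "+") / 2
  depths <- array(0, dim = c(nx, ny, 11L))
  depths[, , 1] <- spec$vitreous_depth_um / zres + bowl
  for (i in seq_along(oct_layers()))
    depths[, , i + 1L] <- depths[, , i] + maps[[i]] / zres
  surface_set(depths)
}

#' Generate a synthetic OCT volume with known ground truth
#'
#' Builds the true surfaces from the spec's thickness model, fills each voxel
#' with the two-way Beer-Lambert expected intensity (voxel-centre midpoint
#' rule along z, half-open slab assignment `[ceil(top), ceil(bottom))`),
#' applies unit-mean Gamma speckle if requested, and clips to the 16-bit
#' range. The returned `truth` records the exact surfaces, per-layer `mu`,
#' thickness maps and the quality score implied by the speckle shape.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `volume` ([oct_volume()]) and `truth`
#'   (class `phantom_truth`: `surfaces`, `mu_by_layer`, `backscatter`,
#'   `thickness_maps`, `fovea_index`, `quality_score`).
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  maps <- .thickness_maps(spec)
  surfaces <- .surfaces_from_thickness(spec, maps)
  nz <- spec$grid_shape[3]
  if (max(surfaces) >= nz - 1)
    stop(sprintf(paste0("grid too small: deepest surface at voxel %.1f ",
                        "does not fit in %d depth voxels"),
                 max(surfaces), nz))
  vol <- .render_volume(spec, surfaces)
  q <- .quality_from_shape(spec$speckle_shape, spec$quality_shape_ref)
  truth <- structure(list(
    surfaces = surfaces,
    mu_by_layer = spec$attenuation,
    backscatter = spec$backscatter,
    thickness_maps = maps,
    fovea_index = attr(maps, "fovea_index"),
    quality_score = q,
    spec = spec), class = "phantom_truth")
  volume <- oct_volume(vol, spec$voxel_size, spec$laterality,
                       quality_score = q, subject_id = spec$subject_id)
  list(volume = volume, truth = truth)
}

# voxelize the Beer-Lambert model, one B-scan at a time to bound memory
.render_volume <- function(spec, surfaces) {
  d <- spec$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  zres_mm <- spec$voxel_size[3] / 1000
  b_lut <- c(spec$vitreous$backscatter, unname(spec$backscatter),
             spec$sub_rpe$backscatter)
  mu_lut <- c(spec$vitreous$mu, unname(spec$attenuation), spec$sub_rpe$mu)
  out <- array(0, dim = d)
  z0 <- 0:(nz - 1)
  su <- unclass(surfaces)
  for (y in seq_len(ny)) {
    region <- matrix(0L, nx, nz)
    for (k in 1:11) {
      cs <- ceiling(su[, y, k])
      region <- region + (matrix(z0, nx, nz, byrow = TRUE) >=
                            matrix(cs, nx, nz))
    }
    mu <- matrix(mu_lut[region + 1L], nx, nz)
    bsc <- matrix(b_lut[region + 1L], nx, nz)
    cum <- t(apply(mu, 1L, cumsum))
    expected <- spec$incident * bsc * exp(-2 * zres_mm * (cum - mu / 2))
    if (is.finite(spec$speckle_shape)) {
      k <- spec$speckle_shape
      expected <- expected * matrix(stats::rgamma(nx * nz, shape = k, rate = k),
                                    nx, nz)
    }
    out[, y, ] <- pmin(pmax(round(expected), 0), 65535)
  }
  out
}

#' Closed-form noise-free layer signals per A-line
#'
#' Evaluates the generator's continuous Beer-Lambert model analytically: for
#' each A-line and each of the ten layers, the depth-integrated signal
#' `S_l = I0 * b_l * exp(-2 A_l) * (1 - exp(-2 mu_l d_l)) / (2 mu_l)`
#' (in AU * mm; `A_l` is the one-way optical depth above the layer including
#' the vitreous) and the mean intensity `S_l / d_l` (AU). This is the exact
#' expectation of what the voxel path measures, and is the fast route used
#' for cohort-scale simulation.
#'
#' @param surfaces a [surface_set()] (fractional voxel depths).
#' @param optics list with named vectors `attenuation` (1/mm) and
#'   `backscatter` over [oct_layers()], plus `vitreous` (list `mu`,
#'   `backscatter`) and `incident` (AU); a [phantom_spec()] works.
#' @param voxel_size length-3 voxel pitch in um.
#' @return List of two `nx x ny x 10` arrays, `integral` and `mean`, with
#'   layer names on the third dimension.
#' @export
expected_layer_signals <- function(surfaces, optics, voxel_size) {
  ln <- oct_layers()
  zres_mm <- voxel_size[3] / 1000
  su <- unclass(surfaces)
  nx <- dim(su)[1]; ny <- dim(su)[2]
  S <- array(0, dim = c(nx, ny, 10L), dimnames = list(NULL, NULL, ln))
  M <- S
  A <- su[, , 1] * zres_mm * optics$vitreous$mu  # optical depth above ILM
  for (i in seq_along(ln)) {
    mu <- optics$attenuation[[ln[i]]]
    b <- optics$backscatter[[ln[i]]]
    d <- (su[, , i + 1L] - su[, , i]) * zres_mm
    x <- 2 * mu * d
    shape_term <- ifelse(x < 1e-12, d, (1 - exp(-x)) / (2 * mu))
    S[, , i] <- optics$incident * b * exp(-2 * A) * shape_term
    M[, , i] <- ifelse(d > 0, S[, , i] / d, 0)
    A <- A + mu * d
  }
  list(integral = S, mean = M)
}

#' Per-A-line layer signals from ground truth, with speckle-equivalent noise
#'
#' Evaluates [expected_layer_signals()] on a `phantom_truth` (using the
#' subject's own optics) and, if requested, multiplies each layer integral
#' by a Gamma draw with shape `n_voxels * speckle_shape` — the distribution
#' of a sum of that many unit-mean Gamma speckle voxels — so truth-mode
#' quantification carries the same first- and second-order noise structure
#' as integrating a rendered volume.
#'
#' @param truth a `phantom_truth` (from [generate_volume()] or
#'   [generate_cohort()]).
#' @param measurement_noise logical.
#' @return `nx x ny x 10` array of layer integrals (AU * mm).
#' @export
sampled_layer_signals <- function(truth, measurement_noise = TRUE) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  sig <- expected_layer_signals(truth$surfaces, spec, spec$voxel_size)
  S <- sig$integral
  if (measurement_noise && is.finite(spec$speckle_shape)) {
    zres <- spec$voxel_size[3]
    for (i in seq_len(dim(S)[3])) {
      nvox <- pmax(truth$thickness_maps[[i]] / zres, 1)
      shp <- nvox * spec$speckle_shape
      S[, , i] <- S[, , i] *
        matrix(stats::rgamma(length(shp), shape = shp, rate = shp),
               nrow = dim(S)[1])
    }
  }
  S
}

# ---- cohorts ---------------------------------------------------------------

#' Two-group cohort specification
#'
#' Describes a patient/control cohort of phantom eyes. Patient-group effects
#' are expressed as per-layer, per-quadrant additive thickness deltas (um)
#' and per-layer attenuation deltas (1/mm); defaults emulate a chiasmal
#' compression pattern: nasal-predominant mRNFL thinning with smaller GCIPL
#' thinning, and a small mRNFL attenuation increase. Between-subject
#' variation combines a global multiplicative thickness factor, per-layer
#' additive offsets, per-layer attenuation offsets, a quality score drawn
#' around the device-typical 70 +/- 6.5, and per-layer backscatter
#' variability in which every layer except the designated
#' `quality_independent_layer` is coupled to the quality score (this designed
#' structure is what the reference-layer selection procedure recovers).
#'
#' @param n_patient,n_control group sizes (default 38 / 39).
#' @param grid_shape,voxel_size phantom geometry for each subject (truth-mode
#'   cohorts only need the transverse grid; see [generate_cohort()]).
#' @param thickness_deltas named list: layer -> named numeric over
#'   `c("SN","IN","ST","IT")`, additive um applied to patients.
#' @param mu_deltas named numeric, additive 1/mm applied to patients.
#' @param thickness_sd named numeric, per-layer between-subject SD (um).
#' @param global_thickness_sd SD of the shared multiplicative factor.
#' @param mu_sd named numeric, per-layer between-subject SD of `mu` (1/mm).
#' @param quality_mean,quality_sd quality-score distribution.
#' @param quality_coupling named numeric over `c("vitreous", oct_layers())`:
#'   relative backscatter change per 100 quality units.
#' @param backscatter_sd named numeric, residual relative SD of per-subject
#'   backscatter (the quality-independent layer's small value gives it the
#'   lowest quality-adjusted coefficient of variation by design).
#' @param quality_independent_layer layer whose backscatter is decoupled from
#'   quality (default `"RPE"`, matching its assumed uniform scattering).
#' @param fovea_jitter_mm SD of the random transverse fovea offset.
#' @param measurement_noise logical; add per-A-line noise on truth-mode layer
#'   integrals with the relative SD implied by the speckle model
#'   (`1/sqrt(n_voxels * shape)`).
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patient = 38L, n_control = 39L,
                        grid_shape = c(64L, 32L, 256L),
                        voxel_size = NULL,
                        thickness_deltas = list(
                          RNFL = c(SN = -4.2, IN = -5.1, ST = -1.5, IT = -1.3),
                          GCL  = c(SN = -1.2, IN = -1.4, ST = -0.1, IT = 0.1),
                          IPL  = c(SN = -1.2, IN = -1.4, ST = -0.1, IT = 0.1)),
                        mu_deltas = c(RNFL = 0.20, GCL = 0.02, IPL = 0.02),
                        thickness_sd = c(RNFL = 2.5, GCL = 2.0, IPL = 2.0,
                                         INL = 2.0, OPL = 2.0, ONL = 4.0,
                                         ELM = 1.0, ISOS = 1.5, OS = 1.5,
                                         RPE = 1.5),
                        global_thickness_sd = 0.03,
                        mu_sd = c(RNFL = 0.35, GCL = 0.18, IPL = 0.18,
                                  INL = 0.3, OPL = 0.3, ONL = 0.3,
                                  ELM = 0.3, ISOS = 0.3, OS = 0.3, RPE = 0.5),
                        quality_mean = 70, quality_sd = 6.5,
                        quality_coupling = NULL,
                        backscatter_sd = NULL,
                        quality_independent_layer = "RPE",
                        fovea_jitter_mm = 0.15,
                        measurement_noise = TRUE,
                        seed = 1L) {
  stopifnot(n_patient >= 2L, n_control >= 2L)
  stopifnot(all(unlist(thickness_sd) >= 0), all(mu_sd >= 0),
            global_thickness_sd >= 0)
  ln <- oct_layers()
  if (is.null(quality_coupling)) {
    quality_coupling <- c(vitreous = 0.20,
                          stats::setNames(rep(0.45, 10), ln))
    quality_coupling[quality_independent_layer] <- 0
  }
  if (is.null(backscatter_sd)) {
    backscatter_sd <- c(vitreous = 0.02, stats::setNames(rep(0.02, 10), ln))
    backscatter_sd[quality_independent_layer] <- 0.005
  }
  structure(list(
    n_patient = as.integer(n_patient), n_control = as.integer(n_control),
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    thickness_deltas = thickness_deltas, mu_deltas = mu_deltas,
    thickness_sd = thickness_sd, global_thickness_sd = global_thickness_sd,
    mu_sd = mu_sd, quality_mean = quality_mean, quality_sd = quality_sd,
    quality_coupling = quality_coupling, backscatter_sd = backscatter_sd,
    quality_independent_layer = quality_independent_layer,
    fovea_jitter_mm = fovea_jitter_mm,
    measurement_noise = isTRUE(measurement_noise),
    seed = as.integer(seed)), class = "cohort_spec")
}

# full-plane quadrant labels (no "outside"), used to apply group deltas
.hemifield_labels <- function(nx, ny, fx, fy, laterality) {
  nasal_sign <- if (laterality == "OD") 1 else -1
  dx <- matrix(seq_len(nx) - fx, nx, ny)
  dy <- matrix(seq_len(ny) - fy, nx, ny, byrow = TRUE)
  nasal <- nasal_sign * dx >= 0
  superior <- dy < 0
  lab <- matrix("IT", nx, ny)
  lab[superior & nasal] <- "SN"
  lab[!superior & nasal] <- "IN"
  lab[superior & !nasal] <- "ST"
  lab
}

#' Generate a two-group phantom cohort
#'
#' Draws per-subject generative parameters (thickness offsets, attenuation,
#' quality score, backscatter factors, age, sex, laterality, fovea position),
#' applies the patient-group deltas, and returns one entry per subject with
#' its ground truth. With `volumes = TRUE`, full voxel volumes are rendered
#' for every subject; by default only the truth (surfaces, optics, thickness
#' maps) is built, which is exact for thickness and, via
#' [expected_layer_signals()], for the noise-free intensity model, and is the
#' scale at which replicated cohort studies run.
#'
#' Thicknesses that would go negative after deltas are clamped at one voxel
#' and counted in the subject's `clamped` tally. Identical specs (same seed)
#' reproduce the cohort bit-exactly.
#'
#' @param cohort a [cohort_spec()].
#' @param volumes logical; render full voxel volumes.
#' @return A list of class `oct_cohort`; each element has `meta` (subject_id,
#'   group, age, sex, laterality, quality), `truth` and (optionally)
#'   `volume`. The metadata table is available via [cohort_meta()].
#' @export
generate_cohort <- function(cohort, volumes = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$seed)
  n <- cohort$n_patient + cohort$n_control
  groups <- rep(c("patient", "control"), c(cohort$n_patient, cohort$n_control))
  ln <- oct_layers()
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    # demographics emulate the study's reported distributions
    age <- if (g == "patient") {
      min(max(stats::rnorm(1, 44.7, 13.8), 8), 72)
    } else {
      min(max(stats::rnorm(1, 40.8, 11.9), 23), 71)
    }
    sex <- sample(c("M", "F"), 1,
                  prob = if (g == "patient") c(21, 17) else c(19, 20))
    lat <- sample(c("OS", "OD"), 1,
                  prob = if (g == "patient") c(25, 13) else c(24, 15))
    q <- min(max(stats::rnorm(1, cohort$quality_mean, cohort$quality_sd),
                 40), 95)
    shape <- .shape_from_quality(q)
    # subject phantom spec
    spec <- phantom_spec(grid_shape = cohort$grid_shape,
                         voxel_size = cohort$voxel_size,
                         fovea = list(
                           offset_mm = stats::rnorm(2, 0, cohort$fovea_jitter_mm),
                           pit_depth_um = 90, pit_radius_mm = 0.6),
                         speckle_shape = shape,
                         laterality = lat,
                         subject_id = sprintf("S%03d", i),
                         seed = cohort$seed + 1000L + i)
    # between-subject thickness variation
    gf <- stats::rnorm(1, 1, cohort$global_thickness_sd)
    spec$layer_thickness <- spec$layer_thickness * gf +
      stats::rnorm(10, 0, cohort$thickness_sd[ln])
    spec$layer_thickness <- pmax(spec$layer_thickness, spec$voxel_size[3])
    # attenuation variation + patient deltas
    mu <- spec$attenuation + stats::rnorm(10, 0, cohort$mu_sd[ln])
    if (g == "patient")
      for (l in names(cohort$mu_deltas))
        mu[l] <- mu[l] + cohort$mu_deltas[[l]]
    spec$attenuation <- pmax(mu, 0.05)
    # quality-coupled backscatter with per-layer residual variability
    qc <- cohort$quality_coupling
    bs_sd <- cohort$backscatter_sd
    fac <- function(nm) (1 + qc[[nm]] * (q - cohort$quality_mean) / 100) *
      (1 + stats::rnorm(1, 0, bs_sd[[nm]]))
    spec$backscatter <- spec$backscatter *
      vapply(ln, fac, numeric(1))
    spec$backscatter <- pmin(pmax(spec$backscatter, 1e-3), 1)
    spec$vitreous$backscatter <- spec$vitreous$backscatter * fac("vitreous")
    # quadrant thickness deltas for patients
    offsets <- NULL
    if (g == "patient" && length(cohort$thickness_deltas)) {
      fxy <- c((spec$grid_shape[1] + 1) / 2 +
                 spec$fovea$offset_mm[1] * 1000 / spec$voxel_size[1],
               (spec$grid_shape[2] + 1) / 2 +
                 spec$fovea$offset_mm[2] * 1000 / spec$voxel_size[2])
      lab <- .hemifield_labels(spec$grid_shape[1], spec$grid_shape[2],
                               fxy[1], fxy[2], lat)
      offsets <- lapply(cohort$thickness_deltas, function(dq) {
        m <- matrix(0, spec$grid_shape[1], spec$grid_shape[2])
        for (r in REGIONS) m[lab == r] <- dq[[r]]
        m
      })
    }
    set.seed(spec$seed)  # subject-local stream for maps/volume
    maps <- .thickness_maps(spec, offsets = offsets)
    clamped <- sum(vapply(maps, function(m)
      sum(m <= spec$voxel_size[3] + 1e-12), numeric(1)))
    surfaces <- .surfaces_from_thickness(spec, maps)
    truth <- structure(list(
      surfaces = surfaces, mu_by_layer = spec$attenuation,
      backscatter = spec$backscatter, thickness_maps = maps,
      fovea_index = attr(maps, "fovea_index"),
      quality_score = q, spec = spec), class = "phantom_truth")
    vol <- NULL
    if (volumes) {
      if (max(surfaces) >= spec$grid_shape[3] - 1)
        stop("grid too small for subject ", spec$subject_id)
      arr <- .render_volume(spec, surfaces)
      vol <- oct_volume(arr, spec$voxel_size, lat, q, spec$subject_id)
    }
    subjects[[i]] <- list(
      meta = list(subject_id = spec$subject_id, group = g, age = age,
                  sex = sex, laterality = lat, quality = q,
                  clamped_alines = clamped),
      truth = truth, volume = vol)
  }
  structure(subjects, class = "oct_cohort", spec = cohort)
}

#' Cohort metadata table
#'
#' @param cohort an `oct_cohort` from [generate_cohort()].
#' @return Data frame with one row per subject
#'   (`subject_id, group, age, sex, laterality, quality`).
#' @export
cohort_meta <- function(cohort) {
  stopifnot(inherits(cohort, "oct_cohort"))
  do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$meta$subject_id, group = s$meta$group,
               age = s$meta$age, sex = s$meta$sex,
               laterality = s$meta$laterality, quality = s$meta$quality,
               stringsAsFactors = FALSE)))
}

#' Simulate per-subject layer mean intensities for reference-layer studies
#'
#' Draws the designed generative structure behind the reference-layer
#' selection procedure directly at the summary level: subject quality scores
#' `q ~ N(mean, sd)` and, for each candidate layer, mean intensity
#' `I_l = base_l * (1 + coupling_l * (q - mean)/100 + resid_l)` with
#' independent Gaussian residuals. One layer (default RPE) has zero coupling
#' and a small residual SD, making it the designed quality-independent
#' reference.
#'
#' @param n subjects.
#' @param cohort a [cohort_spec()] supplying coupling and residual SDs.
#' @param base named numeric of base mean intensities over
#'   `c("vitreous", oct_layers())`; defaults derive from the phantom's
#'   nominal noise-free profile.
#' @param seed integer seed.
#' @return List with `intensity` (n x 11 matrix) and `quality` (length n).
#' @export
simulate_intensity_cohort <- function(n, cohort = cohort_spec(),
                                      base = NULL, seed = 1L) {
  set.seed(seed)
  nm <- c("vitreous", oct_layers())
  if (is.null(base)) base <- nominal_layer_means()
  stopifnot(all(nm %in% names(base)))
  q <- stats::rnorm(n, cohort$quality_mean, cohort$quality_sd)
  int <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  for (l in nm) {
    cc <- cohort$quality_coupling[[l]]
    sd <- cohort$backscatter_sd[[l]]
    int[, l] <- base[[l]] *
      (1 + cc * (q - cohort$quality_mean) / 100 + stats::rnorm(n, 0, sd))
  }
  list(intensity = int, quality = q)
}

#' @rdname simulate_intensity_cohort
#' @export
nominal_layer_means <- function(spec = phantom_spec()) {
  ln <- oct_layers()
  zres_mm <- spec$voxel_size[3] / 1000
  d <- spec$layer_thickness / 1000
  A <- spec$vitreous_depth_um / 1000 * spec$vitreous$mu
  out <- c(vitreous = spec$incident * spec$vitreous$backscatter)
  for (l in ln) {
    mu <- spec$attenuation[[l]]
    x <- 2 * mu * d[[l]]
    S <- spec$incident * spec$backscatter[[l]] * exp(-2 * A) *
      (1 - exp(-x)) / (2 * mu)
    out[l] <- S / d[[l]]
    A <- A + mu * d[[l]]
  }
  out
}
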