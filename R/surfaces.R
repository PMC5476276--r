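# Simplified surface segmentation (per-B-scan dynamic programming on a
# signed-gradient cost), volume flattening, and segmentation QC.

#' Segmentation configuration
#'
#' The segmenter finds the eleven boundaries sequentially from the top of the
#' scan. Each boundary is a per-B-scan shortest path through a signed axial
#' gradient cost (median-smoothed along depth, boxcar-smoothed along the fast
#' axis), constrained to change by at most `smoothness` voxels between
#' neighbouring A-lines and restricted to a search band placed relative to
#' the previously found boundary. Because band offsets are non-negative,
#' non-crossing is guaranteed by construction.
#'
#' @param smoothness maximum inter-A-line depth change in voxels.
#' @param signs length-11 vector in `{-1, +1}`: expected gradient direction
#'   at each boundary (+1 = intensity increases with depth, dark over
#'   bright). Defaults derive from the phantom's default backscatter
#'   sequence.
#' @param gap_min,gap_max length-11 integer vectors: per-A-line search band
#'   for boundary k relative to boundary k-1 (boundary 1 is searched from the
#'   scan top). Inner boundaries allow a zero gap so the foveal pit is
#'   representable.
#' @param median_window depth median-filter window (odd).
#' @param xsmooth boxcar width for cost smoothing along the fast axis (odd).
#' @param min_contrast minimum gradient magnitude (AU) for a B-scan to count
#'   as featured; below it the B-scan is QC-failed rather than guessed.
#' @param nominal_thickness_um named per-layer nominal thicknesses used to
#'   build default bands.
#' @param z_res_um depth pitch used to convert them to voxels.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(smoothness = 2L,
                                signs = NULL,
                                gap_min = NULL, gap_max = NULL,
                                median_window = 3L,
                                xsmooth = 5L,
                                min_contrast = 30,
                                nominal_thickness_um = default_layer_thickness(),
                                z_res_um = 2.3) {
  stopifnot(smoothness >= 0, median_window %% 2 == 1, xsmooth %% 2 == 1)
  if (is.null(signs)) {
    b <- c(0.02, unname(default_backscatter()), 0.30)
    signs <- sign(diff(b))
  }
  tv <- nominal_thickness_um[oct_layers()] / z_res_um
  if (is.null(gap_min)) {
    gap_min <- c(2, rep(0, 3), pmax(1, floor(0.35 * tv[4:10])))
  }
  if (is.null(gap_max)) {
    gap_max <- c(NA, ceiling(2.0 * tv) + 4)  # NA: boundary 1 band set from nz
  }
  stopifnot(length(signs) == 11L, length(gap_min) == 11L,
            length(gap_max) == 11L)
  if (any(gap_min[-1] > gap_max[-1], na.rm = TRUE))
    stop("degenerate search band: gap_min > gap_max")
  structure(list(smoothness = as.integer(smoothness), signs = signs,
                 gap_min = as.numeric(gap_min), gap_max = as.numeric(gap_max),
                 median_window = as.integer(median_window),
                 xsmooth = as.integer(xsmooth),
                 min_contrast = min_contrast),
            class = "segmentation_config")
}

# boxcar smoothing along rows (fast axis) with edge replication
.boxcar_x <- function(M, w) {
  if (w <= 1L) return(M)
  h <- (w - 1L) %/% 2L
  nx <- nrow(M)
  P <- rbind(M[rep(1L, h), , drop = FALSE], M,
             M[rep(nx, h), , drop = FALSE])
  cs <- apply(P, 2L, cumsum)
  (cs[w:(nx + w - 1L), , drop = FALSE] -
     rbind(0, cs[seq_len(nx - 1L), , drop = FALSE])) / w
}

# median filter of odd window along columns (depth) via running median per row
.median_z <- function(M, w) {
  if (w <= 1L) return(M)
  t(apply(M, 1L, function(r) stats::runmed(r, w, endrule = "median")))
}

# DP shortest path across the fast axis for one boundary on one B-scan.
# cost: nx x np matrix (np = candidate interface positions), Inf = forbidden.
.dp_path <- function(cost, sm) {
  nx <- nrow(cost); np <- ncol(cost)
  M <- cost
  for (x in 2:nx) {
    prev <- M[x - 1L, ]
    best <- prev
    if (sm > 0) for (s in seq_len(sm)) {
      best <- pmin(best,
                   c(prev[-seq_len(s)], rep(Inf, s)),
                   c(rep(Inf, s), prev[seq_len(np - s)]))
    }
    M[x, ] <- cost[x, ] + best
  }
  path <- integer(nx)
  path[nx] <- which.min(M[nx, ])
  if (nx > 1) for (x in (nx - 1L):1L) {
    lo <- max(1L, path[x + 1L] - sm)
    hi <- min(np, path[x + 1L] + sm)
    path[x] <- lo - 1L + which.min(M[x, lo:hi])
  }
  path
}

#' Segment the eleven retinal surfaces
#'
#' Per-B-scan dynamic-programming stand-in for full 3D graph segmentation:
#' adequate for phantom-like data, and replaceable by externally supplied
#' surfaces ([read_surfaces()]) for anything harder. Returns integer-voxel
#' boundary estimates (0-based, matching the half-open slab convention).
#' B-scans whose gradient contrast falls below `config$min_contrast` are
#' flagged as QC-failed; if every B-scan fails, no surfaces are returned.
#'
#' @param volume an [oct_volume()].
#' @param config a [segmentation_config()].
#' @return List of class `segmentation_result`: `surfaces` (a
#'   [surface_set()], or `NULL` if nothing was segmentable) and `qc` (data
#'   frame with one row per B-scan: `bscan`, `featureless`, `n_band_edge`).
#' @export
segment_surfaces <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  depths <- array(NA_real_, dim = c(nx, ny, 11L))
  featureless <- logical(ny)
  band_edge <- integer(ny)
  gmax1 <- round(0.6 * nz)
  for (y in seq_len(ny)) {
    I <- .median_z(volume$intensity[, y, , drop = TRUE], config$median_window)
    fd <- I[, 2:nz, drop = FALSE] - I[, 1:(nz - 1L), drop = FALSE]
    fd <- .boxcar_x(fd, config$xsmooth)
    if (max(abs(fd)) < config$min_contrast) {
      featureless[y] <- TRUE
      next
    }
    prev <- NULL
    for (k in 1:11) {
      if (k == 1L) {
        lo_x <- rep(config$gap_min[1], nx)
        hi_x <- rep(gmax1, nx)
      } else {
        lo_x <- prev + config$gap_min[k]
        hi_x <- prev + config$gap_max[k]
      }
      lo_x <- pmin(pmax(lo_x, 1), nz - 1L)
      hi_x <- pmin(pmax(hi_x, lo_x), nz - 1L)
      zr <- min(lo_x):max(hi_x)
      cost <- -config$signs[k] * fd[, zr, drop = FALSE]
      # forbid out-of-band cells per A-line
      Z <- matrix(zr, nx, length(zr), byrow = TRUE)
      cost[Z < lo_x | Z > hi_x] <- Inf
      p <- .dp_path(cost, config$smoothness)
      prev_new <- zr[p]
      if (k > 1L)
        band_edge[y] <- band_edge[y] +
          sum(prev_new == lo_x & config$gap_min[k] > 0) + sum(prev_new == hi_x)
      prev <- prev_new
      depths[, y, k] <- prev
    }
  }
  qc <- data.frame(bscan = seq_len(ny), featureless = featureless,
                   n_band_edge = band_edge)
  if (all(featureless)) {
    return(structure(list(surfaces = NULL, qc = qc),
                     class = "segmentation_result"))
  }
  # fill failed B-scans from the nearest segmented neighbour
  if (any(featureless)) {
    good <- which(!featureless)
    for (y in which(featureless)) {
      nb <- good[which.min(abs(good - y))]
      depths[, y, ] <- depths[, nb, ]
    }
  }
  structure(list(surfaces = surface_set(depths), qc = qc),
            class = "segmentation_result")
}

#' Flatten a volume against a reference boundary
#'
#' Shifts every A-line by an integer number of voxels so the chosen boundary
#' sits at a constant target depth; all surfaces are shifted identically.
#' Because shifts are whole voxels, voxel counts (and hence thickness maps)
#' between any two boundaries are unchanged bit-for-bit. Depth bins exposed
#' by the shift are padded with 0 AU and the padding is flagged on the
#' returned volume.
#'
#' @param volume an [oct_volume()].
#' @param surfaces a [surface_set()] for the same grid.
#' @param reference_boundary boundary name anchoring the flattening; default
#'   `"OS_RPE"` (the bottom of the photoreceptor inner/outer segment
#'   complex).
#' @param target target depth (0-based voxels); default the rounded median
#'   reference depth.
#' @return List: `volume` (flattened), `surfaces` (shifted), `shifts`
#'   (`nx x ny` integer matrix), `padded` (logical).
#' @export
flatten <- function(volume, surfaces, reference_boundary = "OS_RPE",
                    target = NULL) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "surface_set"))
  if (!reference_boundary %in% oct_boundaries())
    stop("unknown reference boundary: ", reference_boundary)
  ref <- unclass(surfaces)[, , reference_boundary]
  if (is.null(target)) target <- round(stats::median(ref))
  shifts <- round(ref - target)
  d <- dim(volume$intensity)
  nz <- d[3]
  out <- array(0, dim = d)
  padded <- any(shifts != 0)
  for (y in seq_len(d[2])) {
    for (x in seq_len(d[1])) {
      s <- shifts[x, y]
      if (s == 0L) {
        out[x, y, ] <- volume$intensity[x, y, ]
      } else {
        src <- (1:nz) + s
        ok <- src >= 1L & src <= nz
        out[x, y, which(ok)] <- volume$intensity[x, y, src[ok]]
      }
    }
  }
  new_depths <- unclass(surfaces) - array(shifts, dim = dim(surfaces))
  flat_vol <- oct_volume(out, volume$voxel_size, volume$laterality,
                         volume$quality_score, volume$subject_id)
  flat_vol$padded <- padded
  list(volume = flat_vol, surfaces = surface_set(new_depths),
       shifts = shifts, padded = padded)
}

#' Per-B-scan segmentation quality report
#'
#' Automated surrogate for manual review: flags B-scans whose surfaces cross
#' (should be impossible for the built-in segmenter), whose total-retina
#' thickness leaves a plausible range, or whose inner-layer (GCC) thickness
#' collapses to zero over a large fraction of A-lines (more than a foveal pit
#' explains). Downstream aggregation can exclude flagged B-scans.
#'
#' @param surfaces a [surface_set()].
#' @param volume the corresponding [oct_volume()] (supplies z pitch).
#' @param total_range plausible total-retina thickness range in um.
#' @param max_zero_frac maximum tolerated fraction of near-zero-GCC A-lines
#'   per B-scan.
#' @return Data frame: `bscan`, `crossing`, `implausible_total`,
#'   `inner_collapse`, `flagged`.
#' @export
qc_report <- function(surfaces, volume, total_range = c(150, 450),
                      max_zero_frac = 0.3) {
  stopifnot(inherits(surfaces, "surface_set"))
  zres <- volume$voxel_size[3]
  su <- unclass(surfaces)
  ny <- dim(su)[2]
  total <- (ceiling(su[, , "BM"]) - ceiling(su[, , "ILM"])) * zres
  gcc <- (ceiling(su[, , "IPL_INL"]) - ceiling(su[, , "ILM"])) * zres
  crossing <- logical(ny); imp <- logical(ny); collapse <- logical(ny)
  for (y in seq_len(ny)) {
    dif <- su[, y, -1, drop = TRUE] - su[, y, -11, drop = TRUE]
    crossing[y] <- any(dif < -1e-9)
    imp[y] <- mean(total[, y] < total_range[1] |
                     total[, y] > total_range[2]) > 0.1
    collapse[y] <- mean(gcc[, y] < zres + 1e-9) > max_zero_frac
  }
  data.frame(bscan = seq_len(ny), crossing = crossing,
             implausible_total = imp, inner_collapse = collapse,
             flagged = crossing | imp | collapse)
}
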