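# Fovea localization, the 5.0 mm fovea-centered square, and SN/IN/ST/IT
# quadrant demarcation with laterality-aware nasal/temporal assignment.

#' Locate the fovea on a segmented surface set
#'
#' The foveal pit is the point where the inner layers vanish, so the A-line
#' minimizing the axial distance between the ILM and the RNFL/GCL interface
#' inside a central en-face window is taken as the fovea. Ties are broken by
#' proximity to the scan centre, then by scan order (fast axis first), which
#' makes the result deterministic under exact symmetry.
#'
#' @param surfaces a [surface_set()].
#' @param voxel_size length-3 voxel pitch in um.
#' @param central_fraction fraction of each en-face axis forming the central
#'   search window (default 1/3, an anatomical prior: the fovea is near the
#'   scan centre in a macular protocol).
#' @param min_relative_pit the window minimum must be below this fraction of
#'   the window median ILM-to-interface distance, otherwise the surface is
#'   considered pit-free and an error asks for a manual override.
#' @return List: `x`, `y` (1-based A-line indices), `x_mm`, `y_mm` (offsets
#'   from the scan centre), `pit_depth_um` (distance at the minimum).
#' @export
locate_fovea <- function(surfaces, voxel_size, central_fraction = 1 / 3,
                         min_relative_pit = 0.75) {
  stopifnot(inherits(surfaces, "surface_set"),
            central_fraction > 0, central_fraction <= 1)
  su <- unclass(surfaces)
  nx <- dim(su)[1]; ny <- dim(su)[2]
  dist <- su[, , "RNFL_GCL"] - su[, , "ILM"]
  hw_x <- max(1L, round(nx * central_fraction / 2))
  hw_y <- max(1L, round(ny * central_fraction / 2))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xr <- max(1L, floor(cx - hw_x)):min(nx, ceiling(cx + hw_x))
  yr <- max(1L, floor(cy - hw_y)):min(ny, ceiling(cy + hw_y))
  win <- dist[xr, yr, drop = FALSE]
  if (min(win) > min_relative_pit * stats::median(win))
    stop(paste0("no foveal pit found in the central window; ",
                "supply the fovea position manually"))
  m <- min(win)
  cand <- which(win <= m + 1e-9, arr.ind = TRUE)
  # tie-break: nearest to scan centre, then first in scan order
  cx_w <- cand[, 1] + xr[1] - 1L
  cy_w <- cand[, 2] + yr[1] - 1L
  d2 <- (cx_w - cx)^2 + (cy_w - cy)^2
  ord <- order(d2, cy_w, cx_w)
  i <- ord[1]
  list(x = cx_w[i], y = cy_w[i],
       x_mm = (cx_w[i] - cx) * voxel_size[1] / 1000,
       y_mm = (cy_w[i] - cy) * voxel_size[2] / 1000,
       pit_depth_um = m * voxel_size[3])
}

#' Demarcate the fovea-centered square into quadrants
#'
#' Lays an axis-aligned square of the given width over the en-face plane,
#' centred at the fovea, and splits it by the vertical and horizontal
#' midlines through the fovea into superonasal (SN), inferonasal (IN),
#' superotemporal (ST) and inferotemporal (IT) quadrants. Assignment uses
#' geometry only: smaller y is superior; the nasal side of the fast axis is
#' determined by laterality (for OD volumes the fast axis runs
#' temporal-to-nasal, for OS the mirror image), and the fovea column/row
#' itself is assigned to the nasal/superior side so that mirroring the
#' volume in x together with an OD/OS flip preserves every label at its
#' anatomical position.
#'
#' @param fovea list with `x`, `y` (1-based A-line indices), e.g. from
#'   [locate_fovea()].
#' @param dims length-2 en-face grid size `(n_x, n_y)`.
#' @param voxel_size length-3 (or 2) voxel pitch in um.
#' @param laterality `"OD"` or `"OS"`.
#' @param width_mm side length of the square (default 5.0 mm).
#' @return Object of class `quadrant_grid`: list with `labels` (`nx x ny`
#'   character matrix over `{"SN","IN","ST","IT","outside"}`), `fovea`,
#'   `width_mm`, `laterality`.
#' @export
make_quadrant_grid <- function(fovea, dims, voxel_size, laterality,
                               width_mm = 5.0) {
  stopifnot(length(dims) == 2L, laterality %in% c("OD", "OS"))
  nx <- dims[1]; ny <- dims[2]
  if (fovea$x < 1 || fovea$x > nx || fovea$y < 1 || fovea$y > ny)
    stop("fovea lies outside the scan")
  hx <- width_mm * 1000 / 2 / voxel_size[1]   # half-width in A-lines
  hy <- width_mm * 1000 / 2 / voxel_size[2]
  dx <- matrix(seq_len(nx) - fovea$x, nx, ny)
  dy <- matrix(seq_len(ny) - fovea$y, nx, ny, byrow = TRUE)
  inside <- abs(dx) <= hx & abs(dy) <= hy
  nasal_sign <- if (laterality == "OD") 1 else -1
  nasal <- nasal_sign * dx >= 0
  superior <- dy < 0
  lab <- matrix("outside", nx, ny)
  lab[inside & superior & nasal] <- "SN"
  lab[inside & !superior & nasal] <- "IN"
  lab[inside & superior & !nasal] <- "ST"
  lab[inside & !superior & !nasal] <- "IT"
  structure(list(labels = lab, fovea = fovea, width_mm = width_mm,
                 laterality = laterality, voxel_size = voxel_size[1:2]),
            class = "quadrant_grid")
}

#' @export
print.quadrant_grid <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(REGIONS, "outside")))
  cat(sprintf("<quadrant_grid> %.1f mm square, %s; fovea (%d, %d)\n",
              x$width_mm, x$laterality, x$fovea$x, x$fovea$y))
  print(tab)
  invisible(x)
}

#' Aggregate an en-face map over quadrants
#'
#' Means of a per-A-line map over each quadrant of the square, plus the
#' global average over all labelled A-lines (the mean over the whole square,
#' not the mean of the four quadrant means, so unequal quadrant sizes after
#' clipping or masking are handled correctly). Masked A-lines (`mask ==
#' FALSE` or `NA` map values) are excluded; a quadrant left empty yields
#' `NA`, never zero.
#'
#' @param map numeric `nx x ny` matrix congruent with the grid.
#' @param grid a [make_quadrant_grid()] result.
#' @param mask optional logical matrix; `FALSE` excludes an A-line.
#' @return List: `values` (named numeric `SN, IN, ST, IT, Average`),
#'   `n` (named counts of contributing A-lines),
#'   `n_excluded` (labelled A-lines dropped by mask/NA).
#' @export
region_values <- function(map, grid, mask = NULL) {
  stopifnot(inherits(grid, "quadrant_grid"),
            all(dim(map) == dim(grid$labels)))
  ok <- !is.na(map)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(map)))
    ok <- ok & mask
  }
  lab <- grid$labels
  vals <- stats::setNames(numeric(5), c(REGIONS, "Average"))
  ns <- stats::setNames(integer(5), c(REGIONS, "Average"))
  for (r in REGIONS) {
    sel <- lab == r & ok
    ns[r] <- sum(sel)
    vals[r] <- if (ns[r] > 0) mean(map[sel]) else NA_real_
  }
  sel <- lab != "outside" & ok
  ns["Average"] <- sum(sel)
  vals["Average"] <- if (ns["Average"] > 0) mean(map[sel]) else NA_real_
  list(values = vals, n = ns,
       n_excluded = sum(lab != "outside" & !ok))
}

#' Export quadrant labels for visual audit
#'
#' Writes the en-face label matrix as CSV (rows = fast axis).
#'
#' @param grid a [make_quadrant_grid()] result.
#' @param path output CSV path.
#' @export
write_quadrant_grid <- function(grid, path) {
  stopifnot(inherits(grid, "quadrant_grid"))
  utils::write.table(grid$labels, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
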