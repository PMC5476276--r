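# Shared naming and slab conventions for the 11 surfaces / 10 layers.

#' Boundary and layer naming conventions
#'
#' The package works with eleven ordered surfaces (depth maps) delimiting ten
#' retinal layers per A-line, from the inner limiting membrane (ILM) down to
#' Bruch's membrane (BM). Surface depths are stored as 0-based fractional
#' voxel indices along z (depth increases from vitreous towards choroid).
#'
#' A layer slab between surfaces `top` and `bottom` occupies the half-open
#' 0-based voxel range `[ceil(top), ceil(bottom))`, so voxel counts between
#' adjacent boundaries tile each A-line exactly and thickness is additive.
#'
#' `oct_boundaries()` returns the eleven surface names in order;
#' `oct_layers()` the ten anatomical layer names; `analysis_layers()` the
#' composite slabs analysed in the pipeline (mRNFL, GCIPL, GCC, total retina),
#' each as a `c(top_boundary, bottom_boundary)` pair.
#'
#' @return Character vectors (or a named list for `analysis_layers()`).
#' @export
oct_boundaries <- function() {
  c("ILM", "RNFL_GCL", "GCL_IPL", "IPL_INL", "INL_OPL", "OPL_ONL",
    "ONL_ELM", "ELM_ISOS", "ISOS_OS", "OS_RPE", "BM")
}

#' @rdname oct_boundaries
#' @export
oct_layers <- function() {
  c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "ELM", "ISOS", "OS", "RPE")
}

#' @rdname oct_boundaries
#' @export
analysis_layers <- function() {
  list(
    mRNFL        = c("ILM", "RNFL_GCL"),
    GCIPL        = c("RNFL_GCL", "IPL_INL"),
    GCC          = c("ILM", "IPL_INL"),
    total_retina = c("ILM", "BM")
  )
}

# quadrant region labels, in reporting order
REGIONS <- c("SN", "IN", "ST", "IT")

#' Resolve a layer name to its bounding surfaces
#'
#' Accepts an anatomical layer (`"RNFL"` ... `"RPE"`), a composite analysis
#' layer (`"mRNFL"`, `"GCIPL"`, `"GCC"`, `"total_retina"`), the pseudo-layer
#' `"vitreous"` (scan top to ILM), or a length-2 character vector of boundary
#' names.
#'
#' @param layer layer name or boundary pair.
#' @return Length-2 character vector `c(top, bottom)`; `"TOP"` denotes the
#'   first voxel of the scan.
#' @export
layer_bounds <- function(layer) {
  if (is.character(layer) && length(layer) == 2L) {
    stopifnot(all(layer %in% c("TOP", oct_boundaries())))
    return(layer)
  }
  stopifnot(is.character(layer), length(layer) == 1L)
  al <- analysis_layers()
  if (layer %in% names(al)) return(al[[layer]])
  if (layer == "vitreous") return(c("TOP", "ILM"))
  bl <- oct_layers()
  i <- match(layer, bl)
  if (is.na(i)) stop("unknown layer: ", layer)
  b <- oct_boundaries()
  c(b[i], b[i + 1L])
}

# top/bottom depth maps (0-based fractional voxels) for a layer
.slab_maps <- function(surfaces, layer) {
  lb <- layer_bounds(layer)
  top <- if (lb[1] == "TOP") {
    array(0, dim = dim(surfaces)[1:2])
  } else {
    surfaces[, , lb[1], drop = TRUE]
  }
  bot <- surfaces[, , lb[2], drop = TRUE]
  list(top = top, bottom = bot)
}
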