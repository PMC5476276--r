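# Containers and open-format I/O for OCT volumes, surface sets and metadata.

#' Construct an OCT volume
#'
#' An `oct_volume` holds a 3D intensity grid indexed `[x, y, z]` (x = fast
#' scan, y = slow scan / B-scan index, z = depth, increasing from vitreous to
#' choroid), in 16-bit-range arbitrary units (AU), together with voxel
#' geometry and acquisition metadata.
#'
#' @param intensity numeric 3D array, values in `[0, 65535]`.
#' @param voxel_size length-3 numeric, voxel pitch in micrometres `(x, y, z)`.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param quality_score scalar device image-quality score (0-100 scale).
#' @param subject_id character identifier.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, voxel_size, laterality = "OD",
                       quality_score = NA_real_, subject_id = "subject") {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3L)
  storage.mode(intensity) <- "double"
  if (any(intensity < 0 | intensity > 65535, na.rm = TRUE))
    stop("intensity values must lie in [0, 65535]")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (!laterality %in% c("OD", "OS"))
    stop("laterality must be 'OD' or 'OS'")
  structure(
    list(intensity = intensity,
         voxel_size = as.numeric(voxel_size),
         laterality = laterality,
         quality_score = as.numeric(quality_score),
         subject_id = as.character(subject_id)),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<oct_volume %s> %dx%dx%d voxels @ %.2fx%.2fx%.2f um, %s, Q=%.1f\n",
              x$subject_id, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$laterality, x$quality_score))
  invisible(x)
}

#' Construct a surface set
#'
#' Eleven ordered depth maps (0-based fractional voxel indices along z), one
#' per boundary of [oct_boundaries()], stored as an `nx x ny x 11` array.
#' Ordering (`surface_k <= surface_{k+1}` at every A-line) is enforced; a
#' violation is reported with the first offending A-line rather than repaired.
#'
#' @param depths `nx x ny x 11` numeric array, or a list of 11 `nx x ny`
#'   matrices named by boundary.
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(depths) {
  bn <- oct_boundaries()
  if (is.list(depths)) {
    stopifnot(all(bn %in% names(depths)))
    depths <- array(unlist(depths[bn], use.names = FALSE),
                    dim = c(dim(depths[[bn[1]]]), length(bn)))
  }
  stopifnot(is.array(depths), length(dim(depths)) == 3L,
            dim(depths)[3] == length(bn))
  dimnames(depths) <- list(NULL, NULL, bn)
  .check_surface_order(depths)
  structure(depths, class = c("surface_set", "array"))
}

.check_surface_order <- function(depths) {
  bn <- dimnames(depths)[[3]]
  for (k in seq_len(dim(depths)[3] - 1L)) {
    bad <- depths[, , k] > depths[, , k + 1L] + 1e-9
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("surfaces cross: %s > %s at A-line (x=%d, y=%d)",
                   bn[k], bn[k + 1L], ij[1], ij[2]))
    }
  }
  invisible(TRUE)
}

#' @export
print.surface_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<surface_set> %d boundaries on %dx%d A-lines, depth range [%.1f, %.1f]\n",
              d[3], d[1], d[2], min(x), max(x)))
  invisible(x)
}

# ---- volume I/O ------------------------------------------------------------

.sidecar_fields <- c("voxel_size_um", "laterality", "quality_score", "subject_id")

#' Write / read an OCT volume in an open format
#'
#' Volumes are stored as multi-page TIFF (one 16-bit grayscale page per
#' B-scan, rows = depth, columns = fast axis) or raw little-endian `uint16`
#' NRRD, chosen by file extension (`.tif`/`.tiff` vs `.nrrd`). Acquisition
#' metadata travels in a JSON sidecar with fields `voxel_size_um`,
#' `laterality`, `quality_score` and `subject_id`. Integer-valued intensities
#' round-trip bit-exactly in both formats; a missing sidecar field or a
#' grid/sidecar dimension mismatch is an error naming the offender.
#'
#' @param volume an [oct_volume()].
#' @param path volume file path (`.tif`, `.tiff` or `.nrrd`).
#' @param sidecar_path JSON sidecar path; defaults to `<path>.json`.
#' @return `read_volume` returns an [oct_volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(volume, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(volume, "oct_volume"))
  fmt <- .volume_format(path)
  d <- dim(volume$intensity)
  if (fmt == "tiff") {
    pages <- lapply(seq_len(d[2]), function(y)
      t(volume$intensity[, y, , drop = TRUE]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("NRRD0004",
             "# Complete NRRD file format specification at:",
             "# http://teem.sourceforge.net/nrrd/format.html",
             "type: unsigned short",
             "dimension: 3",
             sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
             "encoding: raw",
             "endian: little",
             "")
    writeLines(hdr, con, sep = "\n")
    writeBin(as.integer(round(volume$intensity)), con, size = 2L,
             endian = "little")
  }
  meta <- list(voxel_size_um = volume$voxel_size,
               laterality = volume$laterality,
               quality_score = volume$quality_score,
               subject_id = volume$subject_id,
               grid_shape = d)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (!file.exists(sidecar_path)) stop("sidecar not found: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in .sidecar_fields)
    if (is.null(meta[[f]]) || all(is.na(meta[[f]])) && f != "quality_score")
      stop("sidecar missing required field: ", f)
  fmt <- .volume_format(path)
  if (fmt == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); ny <- length(pages)
    arr <- array(0, dim = c(nx, ny, nz))
    for (y in seq_len(ny)) arr[, y, ] <- t(pages[[y]])
  } else {
    arr <- .read_nrrd(path)
  }
  if (!is.null(meta$grid_shape) &&
      !identical(as.integer(meta$grid_shape), as.integer(dim(arr))))
    stop(sprintf("dimension mismatch: sidecar says %s, file holds %s",
                 paste(meta$grid_shape, collapse = "x"),
                 paste(dim(arr), collapse = "x")))
  oct_volume(arr, meta$voxel_size_um, meta$laterality,
             meta$quality_score, meta$subject_id)
}

.volume_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "nrrd") return("nrrd")
  stop("unrecognized volume format (use .tif/.tiff or .nrrd): ", path)
}

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2L) fields[[kv[1]]] <- kv[2]
  }
  if (!identical(fields$type, "unsigned short"))
    stop("unsupported NRRD type: ", fields$type)
  if (!identical(fields$encoding, "raw"))
    stop("unsupported NRRD encoding: ", fields$encoding)
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  n <- prod(sizes)
  raw <- readBin(con, integer(), n = n, size = 2L, signed = FALSE,
                 endian = if (identical(fields$endian, "big")) "big" else "little")
  array(as.numeric(raw), dim = sizes)
}

# ---- surface I/O -----------------------------------------------------------

#' Write / read surface sets
#'
#' Surfaces exchange as a single JSON file (named list of depth matrices,
#' fractional voxels at 3-decimal precision) or as a directory of per-boundary
#' TSV files (`surface_<NAME>.tsv`, rows = fast axis). The ordering invariant
#' is enforced on read; crossing surfaces are an error reporting the first
#' violating A-line.
#'
#' @param surfaces a [surface_set()].
#' @param path `.json` file, or a directory for `format = "tsv"`.
#' @param format `"json"` or `"tsv"`; inferred from `path` on read.
#' @return `read_surfaces` returns a [surface_set()].
#' @export
write_surfaces <- function(surfaces, path, format = c("json", "tsv")) {
  stopifnot(inherits(surfaces, "surface_set"))
  format <- match.arg(format)
  bn <- oct_boundaries()
  if (format == "json") {
    out <- lapply(bn, function(b) round(unclass(surfaces)[, , b], 3))
    names(out) <- bn
    jsonlite::write_json(out, path, digits = NA, matrix = "rowmajor")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (b in bn)
      utils::write.table(round(unclass(surfaces)[, , b], 3),
                         file.path(path, paste0("surface_", b, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(path) {
  bn <- oct_boundaries()
  if (dir.exists(path)) {
    mats <- lapply(bn, function(b) {
      f <- file.path(path, paste0("surface_", b, ".tsv"))
      if (!file.exists(f)) stop("missing surface file: ", f)
      as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    })
    names(mats) <- bn
    mats <- lapply(mats, function(m) {
      dimnames(m) <- NULL
      m
    })
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    missing <- setdiff(bn, names(raw))
    if (length(missing))
      stop("surface file missing boundaries: ", paste(missing, collapse = ", "))
    mats <- lapply(raw[bn], function(m) {
      m <- as.matrix(m)
      dimnames(m) <- NULL
      m
    })
  }
  surface_set(mats)
}

# ---- subject metadata ------------------------------------------------------

#' Write / read per-subject cohort metadata
#'
#' CSV with columns `subject_id, group, age, sex, laterality, quality`.
#' `group` must be `"patient"` or `"control"`; ages must be positive.
#'
#' @param meta data frame with the columns above.
#' @param path CSV path.
#' @return `read_subject_meta` returns the validated data frame.
#' @export
write_subject_meta <- function(meta, path) {
  .check_subject_meta(meta)
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_meta
#' @export
read_subject_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(age = "numeric",
                                         quality = "numeric"))
  .check_subject_meta(meta)
  meta
}

.check_subject_meta <- function(meta) {
  need <- c("subject_id", "group", "age", "sex", "laterality", "quality")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("subject metadata missing columns: ", paste(missing, collapse = ", "))
  if (!all(meta$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  if (!all(meta$age > 0)) stop("ages must be positive")
  if (!all(meta$laterality %in% c("OD", "OS")))
    stop("laterality must be 'OD' or 'OS'")
  invisible(TRUE)
}
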