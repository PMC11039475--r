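#' Voxel volume container
#'
#' A `voxel_volume` couples a 3D numeric grid with its physical voxel size.
#' Voxels are addressed `data[x, y, z]` (1-based); the physical position of
#' voxel centre `(i, j, k)` is `(i - 1, j - 1, k - 1) * voxel_size_um +
#' origin_um`. Only isotropic voxels are supported: the two acquisition
#' scales modelled here are 3.25 um (whole lobe) and 0.65 um (submicron
#' volume of interest).
#'
#' @param data 3D numeric array.
#' @param voxel_size_um physical voxel edge length in micrometres (scalar).
#' @param origin_um physical offset of voxel (1,1,1), length-3 numeric.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size_um, origin_um = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all grid extents must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         origin_um = as.numeric(origin_um)),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.3g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a volume to disk
#'
#' Writes a multi-page TIFF stack (one 16-bit page per z-slice) or a raw
#' binary file of doubles, plus a JSON sidecar holding the voxel size,
#' origin, grid shape and any extra metadata. TIFF output requires integer
#' data in \[0, 65535\].
#'
#' @param volume a [voxel_volume].
#' @param path output file; extension `.tif`/`.tiff` selects TIFF, anything
#'   else raw binary.
#' @param metadata named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, metadata = list()) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$data)
  fmt <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  if (fmt == "tiff") {
    v <- volume$data
    if (min(v) < 0 || max(v) > 65535 || any(abs(v - round(v)) > 1e-9))
      stop("TIFF output requires integer data in [0, 65535]; ",
           "use a .raw path for floating-point volumes")
    pages <- lapply(seq_len(d[3]), function(k) t(round(v[, , k])) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.double(volume$data), con, size = 8)
  }
  side <- c(list(voxel_size_um = volume$voxel_size_um,
                 origin_um = volume$origin_um,
                 shape = d, format = fmt), metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume from disk
#'
#' Reads a TIFF stack or raw binary volume written by [write_volume()] (or
#' any stack accompanied by a JSON sidecar carrying `voxel_size_um`).
#' Refuses input without a voxel size and anisotropic voxel metadata: the
#' whole pipeline assumes isotropic voxels.
#'
#' @param path file written by [write_volume()].
#' @return A [voxel_volume]; the sidecar metadata is attached as
#'   attribute `"metadata"`.
#' @export
read_volume <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar ", sp,
         ": voxel size metadata is required (no silent default)")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  vs <- side$voxel_size_um
  if (is.null(vs)) stop("sidecar has no `voxel_size_um` entry")
  if (length(vs) > 1L) {
    if (length(unique(vs)) > 1L)
      stop("anisotropic voxel metadata (voxel_size_um = ",
           paste(vs, collapse = " x "),
           "): this pipeline assumes isotropic voxels")
    vs <- vs[1]
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
    a <- array(0, dim = d)
    for (k in seq_along(pages)) a[, , k] <- t(pages[[k]]) * 65535
    a <- round(a)
  } else {
    d <- as.integer(side$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    a <- array(readBin(con, "double", n = prod(d), size = 8), dim = d)
  }
  out <- voxel_volume(a, vs, side$origin_um %||% c(0, 0, 0))
  attr(out, "metadata") <- side
  out
}
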