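#' Optoacoustic amplitude volume
#'
#' Container for a 3D optoacoustic amplitude grid. Axes follow the scan
#' geometry: dimension 1 is `x` (fast scan axis), dimension 2 is `y` (slow
#' scan axis), dimension 3 is `z` (depth, increasing downward). Physical
#' coordinates are zero-based: voxel `[i, j, k]` sits at
#' `((i-1)*dx, (j-1)*dy, (k-1)*dz)` micrometres.
#'
#' @param data 3D numeric array (x, y, z).
#' @param voxel numeric length-3, voxel spacing `(dx, dy, dz)` in micrometres.
#' @return An object of class `oa_volume`.
#' @export
oa_volume <- function(data, voxel) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  voxel <- as.numeric(voxel)
  if (length(voxel) != 3 || any(!is.finite(voxel)) || any(voxel <= 0))
    stop("`voxel` must be three positive spacings (dx, dy, dz) in um")
  structure(list(data = data, voxel = voxel), class = "oa_volume")
}

#' @export
print.oa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oa_volume> %d x %d x %d voxels at (%g, %g, %g) um  [%.2f x %.2f x %.2f mm]\n",
    d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
    d[1] * x$voxel[1] / 1000, d[2] * x$voxel[2] / 1000, d[3] * x$voxel[3] / 1000))
  invisible(x)
}

#' @export
dim.oa_volume <- function(x) dim(x$data)

# physical coordinates (um) of voxel centers along one axis
axis_coords <- function(n, d) (seq_len(n) - 1) * d

#' Save / load a volume
#'
#' Volumes are stored as an RDS file with a human-readable JSON sidecar
#' (`<path>.json`) holding the grid metadata. (No TIFF codec is available to
#' this package; the sidecar keeps the on-disk format self-describing.)
#'
#' @param vol an [oa_volume].
#' @param path file path for the RDS payload.
#' @return `save_volume` returns `path` invisibly; `load_volume` the volume.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oa_volume"))
  saveRDS(vol, path)
  meta <- list(class = "oa_volume", dim = dim(vol$data), voxel_um = vol$voxel)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_volume
#' @export
load_volume <- function(path) {
  vol <- readRDS(path)
  stopifnot(inherits(vol, "oa_volume"))
  vol
}

# clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
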