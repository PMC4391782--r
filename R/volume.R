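#' Construct a 3D volume
#'
#' A `volume` is a numeric 3D array carrying voxel size and unit metadata.
#' Units track what the voxel values mean: `"raw"` detector intensity,
#' `"HU"` Hounsfield units under the air = 0 / water = 1000 convention, or
#' `"mgcc"` hydroxyapatite-equivalent mineral density in mg/cc.
#'
#' @param data numeric 3D array (or 2D matrix, promoted to a single slice).
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @param units one of `"raw"`, `"HU"`, `"mgcc"`.
#' @return an object of class `volume`.
#' @export
volume <- function(data, voxel_size_um = 3.84, units = c("raw", "HU", "mgcc")) {
  units <- match.arg(units)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  structure(data, voxel_size_um = voxel_size_um, units = units,
            class = c("volume", "array"))
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume> %d x %d x %d voxels, %.3g um/voxel, units: %s\n",
              d[1], d[2], d[3], attr(x, "voxel_size_um"), attr(x, "units")))
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

vol_units <- function(x) attr(x, "units") %||% "raw"
vol_voxel <- function(x) attr(x, "voxel_size_um") %||% stop("no voxel size")

`%||%` <- function(a, b) if (is.null(a)) b else a

## rebuild a volume with the same metadata but new values/units
vol_like <- function(data, template, units = vol_units(template)) {
  volume(data, voxel_size_um = vol_voxel(template), units = units)
}

#' Write a volume as a multi-page TIFF stack with a JSON sidecar
#'
#' One 32-bit float page per z-slice. TIFF float pages store values scaled to
#' \[0, 1\]; the sidecar records the affine scale (`value_min`, `value_max`)
#' used, plus voxel size, units and any extra metadata, so [read_volume()]
#' restores the original values (to float32 precision).
#'
#' @param vol a [volume()].
#' @param path output path without extension; writes `<path>.tiff` and
#'   `<path>.json`.
#' @param meta optional named list merged into the sidecar (e.g. seed, spec).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, meta = list()) {
  stopifnot(inherits(vol, "volume"))
  vmin <- min(vol); vmax <- max(vol)
  rng <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(seq_len(dim(vol)[3]),
                  function(k) (unclass(vol)[, , k] - vmin) / rng)
  tiff::writeTIFF(pages, paste0(path, ".tiff"), bits.per.sample = 32L)
  sidecar <- c(list(voxel_size_um = vol_voxel(vol), units = vol_units(vol),
                    dim = dim(vol), value_min = vmin, value_max = vmax,
                    hu_convention = "air=0, water=1000"),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path path without extension.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path, ".tiff"), all = TRUE)
  d <- as.integer(side$dim)
  a <- array(0, d)
  rng <- side$value_max - side$value_min
  if (rng <= 0) rng <- 1
  for (k in seq_len(d[3])) a[, , k] <- pages[[k]] * rng + side$value_min
  volume(a, voxel_size_um = side$voxel_size_um, units = side$units)
}
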