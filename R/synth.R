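#' Acquisition parameters for synthetic tomogram generation
#'
#' Describes the virtual scanner: voxel size, additive HU-domain Gaussian
#' noise, detector point-spread blur, and the raw-intensity anchors that
#' define the raw-to-HU affine map (air maps to 0 HU, water to 1000 HU).
#' Blur is applied before noise (point-spread function acts on the signal,
#' counting noise on the detected values).
#'
#' @param voxel_size_um isotropic voxel size, micrometres (default 3.84).
#' @param noise_sd_hu standard deviation of additive Gaussian noise, HU.
#' @param blur_sigma_vox Gaussian blur sigma in voxels (0 = none).
#' @param air_intensity,water_intensity raw intensities of air and water;
#'   arbitrary detector units, must differ.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(voxel_size_um = 3.84, noise_sd_hu = 0,
                             blur_sigma_vox = 0, air_intensity = 100,
                             water_intensity = 612) {
  if (voxel_size_um <= 0) stop("voxel_size_um must be positive")
  if (noise_sd_hu < 0 || blur_sigma_vox < 0)
    stop("noise and blur parameters must be non-negative")
  if (water_intensity == air_intensity)
    stop("air and water intensities must differ")
  structure(list(voxel_size_um = voxel_size_um, noise_sd_hu = noise_sd_hu,
                 blur_sigma_vox = blur_sigma_vox,
                 air_intensity = air_intensity,
                 water_intensity = water_intensity,
                 rng = "Mersenne-Twister via set.seed"),
            class = "acquisition_spec")
}

## inverse of scale_to_hu for the generator
raw_from_hu <- function(hu, acq) {
  acq$air_intensity + hu / 1000 * (acq$water_intensity - acq$air_intensity)
}

#' Default tissue mineral-density parameters
#'
#' Mineral-density means, voxel-level scatter and ranges for the hard-tissue
#' classes the generator emulates (mg/cc). Where a published mean +/- sd was
#' available it is used directly; where only a range was available the mean
#' is the range midpoint and the scatter is a quarter of the range. A CSV
#' copy ships in `inst/extdata/tissue_md_defaults.csv` as an overridable
#' config template.
#'
#' @return data.frame with columns `tissue`, `md_mean`, `md_sd`, `md_min`,
#'   `md_max` (all mg/cc).
#' @export
tissue_md_defaults <- function() {
  data.frame(
    tissue  = c("enamel", "dentin", "cementum", "bone",
                "diseased_cementum", "hypomineralized_dentin",
                "hypermineralized_dentin", "calculus"),
    md_mean = c(2957.5, 1535, 1290, 1115, 1150, 915, 2255, 1525),
    md_sd   = c(68.75, 27.5, 15, 30, 50, 20, 50, 40),
    md_min  = c(2820, 1480, 1240, 570, 1100, 345, 1815, 1290),
    md_max  = c(3095, 1590, 1340, 1415, 1220, 1450, 2740, 1770)
  )
}

#' Default HU-to-MD calibration used by the generators
#'
#' The linear phantom calibration shipped as ground truth for synthesis:
#' slope 0.11 mg/cc per HU, intercept -48.6 mg/cc. The companion gravimetric
#' (ash) line has the same slope with intercept -17.3 mg/cc.
#'
#' @return a [calibration_model()].
#' @export
default_calibration <- function() calibration_model(0.11, -48.6, r_squared = 1)

#' The phantom densities of the default calibration set
#' @return numeric vector, mg/cc.
#' @export
default_phantom_densities <- function() c(0, 250, 500, 747, 750, 1136, 3080)

## ---- separable Gaussian blur ------------------------------------------------

## 1D Gaussian convolution matrix with edge renormalization
gauss_kernel_matrix <- function(n, sigma) {
  r <- ceiling(3 * sigma)
  offs <- -r:r
  g <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- g[ok] / sum(g[ok])
  }
  K
}

blur_axis <- function(a, K, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  out <- K %*% m
  ap2 <- array(out, dim(ap))
  aperm(ap2, order(perm))
}

#' Separable Gaussian blur of a 2D or 3D array
#'
#' Exact truncated-Gaussian convolution (radius 3 sigma) with edge
#' renormalization, applied independently along every axis.
#'
#' @param a numeric array or matrix.
#' @param sigma Gaussian sigma in voxels; 0 returns the input unchanged.
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(a, sigma) {
  if (sigma == 0) return(a)
  d <- dim(a)
  out <- unclass(a)
  for (ax in seq_along(d)) {
    if (d[ax] > 1) out <- blur_axis(out, gauss_kernel_matrix(d[ax], sigma), ax)
  }
  if (inherits(a, "volume")) vol_like(out, a) else out
}

## shared post-processing: HU field -> blurred, noised raw volume
hu_field_to_raw_volume <- function(hu, acq, seed) {
  stochastic <- acq$noise_sd_hu > 0
  if (stochastic && is.null(seed))
    stop("`seed` is required when noise is enabled")
  hu <- gaussian_blur(hu, acq$blur_sigma_vox)
  if (stochastic) {
    set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), sd = acq$noise_sd_hu)
  }
  volume(array(raw_from_hu(hu, acq), dim(hu)),
         voxel_size_um = acq$voxel_size_um, units = "raw")
}

#' Synthesize a phantom calibration volume with known ground truth
#'
#' Places one cylindrical insert per requested density on an air-level
#' background, maps nominal density to HU through the true calibration line,
#' then to raw intensity through the acquisition anchors, applies blur then
#' additive HU-domain noise.
#'
#' @param densities numeric vector of nominal mineral densities, mg/cc,
#'   non-negative.
#' @param acq an [acquisition_spec()].
#' @param calib_truth the true [calibration_model()] used for synthesis.
#' @param dim integer 3-vector of volume dimensions.
#' @param radius_vox insert cylinder radius in voxels (default packs the grid).
#' @param seed integer seed; required whenever `noise_sd_hu > 0`.
#' @return list with `volume` (raw [volume()]) and `truth`: list holding the
#'   insert `labels` array (0 = background), per-insert table (`region_id`,
#'   `md`, `hu`), the true calibration, ROI voxel indices, and the seed.
#' @export
make_phantom_volume <- function(densities, acq = acquisition_spec(),
                                calib_truth = default_calibration(),
                                dim = c(48, 48, 8), radius_vox = NULL,
                                seed = NULL) {
  if (length(densities) == 0L || any(densities < 0))
    stop("densities must be non-empty and non-negative")
  k <- length(densities)
  ncol_grid <- ceiling(sqrt(k))
  nrow_grid <- ceiling(k / ncol_grid)
  cell_x <- dim[1] / nrow_grid
  cell_y <- dim[2] / ncol_grid
  if (is.null(radius_vox)) radius_vox <- floor(min(cell_x, cell_y) / 2) - 1
  if (radius_vox < 1 || 2 * radius_vox + 1 > min(cell_x, cell_y))
    stop("geometry error: inserts would overlap or be empty at this radius")

  hu_air <- 0
  hu <- array(hu_air, dim)
  labels <- array(0L, dim)
  xs <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1])
  ys <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1])
  hu_true <- hu_from_md(densities, calib_truth)
  for (i in seq_len(k)) {
    gr <- (i - 1) %/% ncol_grid
    gc <- (i - 1) %% ncol_grid
    cx <- (gr + 0.5) * cell_x
    cy <- (gc + 0.5) * cell_y
    disk <- (xs - cx)^2 + (ys - cy)^2 <= radius_vox^2
    for (z in seq_len(dim[3])) {
      sl_hu <- hu[, , z]; sl_lab <- labels[, , z]
      if (any(sl_lab[disk] != 0L)) stop("geometry error: inserts overlap")
      sl_hu[disk] <- hu_true[i]; sl_lab[disk] <- i
      hu[, , z] <- sl_hu; labels[, , z] <- sl_lab
    }
  }
  vol <- hu_field_to_raw_volume(hu, acq, seed)
  rois <- lapply(seq_len(k), function(i) which(labels == i))
  names(rois) <- paste0("phantom_", seq_len(k))
  list(volume = vol,
       truth = list(labels = labels,
                    table = data.frame(region_id = seq_len(k),
                                       md = densities, hu = hu_true),
                    calibration = calib_truth, rois = rois, seed = seed))
}

#' Region descriptor for synthetic tissue volumes
#'
#' @param region_id positive integer label.
#' @param md_mean,md_sd mean and voxel-level scatter of mineral density,
#'   mg/cc.
#' @param z,x,y optional integer ranges `c(lo, hi)` bounding an axis-aligned
#'   box; defaults span the full volume.
#' @param gradient `NULL` for a flat region, or
#'   `list(type = "ramp", axis = 3, delta = <mg/cc>)` for a linear ramp of the
#'   regional mean from `md_mean - delta/2` to `md_mean + delta/2` along the
#'   axis. Sharp steps are expressed as two adjacent flat regions.
#' @return a `tissue_region` list.
#' @export
tissue_region <- function(region_id, md_mean, md_sd = 0, z = NULL, x = NULL,
                          y = NULL, gradient = NULL) {
  if (md_mean < 0) stop("md_mean must be non-negative")
  if (md_sd < 0) stop("md_sd must be non-negative")
  structure(list(region_id = as.integer(region_id), md_mean = md_mean,
                 md_sd = md_sd, x = x, y = y, z = z, gradient = gradient),
            class = "tissue_region")
}

#' Synthesize a tissue volume from region descriptors
#'
#' Per region, voxel mineral density is drawn Normal(`md_mean`, `md_sd`),
#' optionally modulated by a linear ramp of the regional mean, then mapped to
#' HU through the true calibration, blurred, noised, and expressed in raw
#' intensity.
#'
#' @param regions list of [tissue_region()] descriptors; regions must not
#'   overlap and must lie inside `dim`.
#' @param acq an [acquisition_spec()].
#' @param calib_truth the true [calibration_model()].
#' @param dim integer 3-vector.
#' @param seed integer seed; required when `md_sd > 0` anywhere or noise is
#'   enabled.
#' @return list with `volume` (raw) and `truth` (label array — 0 where no
#'   region claims a voxel —, per-region table, true calibration, seed).
#' @export
make_tissue_volume <- function(regions, acq = acquisition_spec(),
                               calib_truth = default_calibration(),
                               dim = c(64, 64, 64), seed = NULL) {
  if (inherits(regions, "tissue_region")) regions <- list(regions)
  stochastic <- acq$noise_sd_hu > 0 ||
    any(vapply(regions, function(r) r$md_sd > 0, logical(1)))
  if (stochastic && is.null(seed))
    stop("`seed` is required for stochastic synthesis")
  if (!is.null(seed)) set.seed(seed)

  md <- array(0, dim)
  labels <- array(0L, dim)
  tab <- data.frame(region_id = integer(), md_mean = numeric(),
                    md_sd = numeric())
  rng_or_full <- function(r, n) {
    if (is.null(r)) c(1L, n)
    else {
      r <- as.integer(r)
      if (r[1] < 1 || r[2] > n || r[1] > r[2])
        stop("geometry error: region outside volume bounds")
      r
    }
  }
  for (reg in regions) {
    xr <- rng_or_full(reg$x, dim[1]); yr <- rng_or_full(reg$y, dim[2])
    zr <- rng_or_full(reg$z, dim[3])
    sub_lab <- labels[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2], drop = FALSE]
    if (any(sub_lab != 0L)) stop("geometry error: regions overlap")
    ddim <- c(diff(xr), diff(yr), diff(zr)) + 1L
    mu <- array(reg$md_mean, ddim)
    if (!is.null(reg$gradient) && identical(reg$gradient$type, "ramp")) {
      ax <- reg$gradient$axis %||% 3L
      n <- ddim[ax]
      ramp <- if (n > 1) seq(-0.5, 0.5, length.out = n) * reg$gradient$delta
              else 0
      mu <- mu + array(ramp[slice.index(mu, ax)], ddim)
    }
    vals <- mu
    if (reg$md_sd > 0)
      vals <- vals + array(stats::rnorm(prod(ddim), sd = reg$md_sd), ddim)
    md[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- vals
    labels[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- reg$region_id
    tab <- rbind(tab, data.frame(region_id = reg$region_id,
                                 md_mean = reg$md_mean, md_sd = reg$md_sd))
  }
  hu <- hu_from_md(md, calib_truth)
  ## noise/blur handled jointly; seed for noise continues the stream above
  hu <- gaussian_blur(hu, acq$blur_sigma_vox)
  if (acq$noise_sd_hu > 0)
    hu <- hu + stats::rnorm(length(hu), sd = acq$noise_sd_hu)
  vol <- volume(array(raw_from_hu(hu, acq), dim),
                voxel_size_um = acq$voxel_size_um, units = "raw")
  list(volume = vol,
       truth = list(labels = labels, table = tab,
                    calibration = calib_truth, seed = seed))
}
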