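#' Linear HU-to-mineral-density calibration model
#'
#' Maps Hounsfield units (air = 0, water = 1000 convention) to
#' hydroxyapatite-equivalent mineral density: `MD = slope * HU + intercept`.
#'
#' @param slope mg/cc per HU; must be non-zero.
#' @param intercept mg/cc.
#' @param r_squared coefficient of determination of the fit, if known.
#' @param residuals optional data.frame of per-phantom fit diagnostics
#'   (`phantom_id`, `mean_hu`, `nominal_md`, `fitted_md`, `residual`).
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept, r_squared = NA_real_,
                              residuals = NULL) {
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0)
    stop("invalid calibration: slope must be a non-zero scalar")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, residuals = residuals),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> MD(mg/cc) = %.6g * HU %+.6g", x$slope,
              x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  (r^2 = %.6g)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Scale raw reconstructed intensities to Hounsfield units
#'
#' Affine map anchoring the air reference at 0 HU and the water reference at
#' 1000 HU: `HU = 1000 * (I - I_air) / (I_water - I_air)`. Values outside the
#' reference interval extrapolate linearly, so mineralized tissue exceeds
#' 1000 HU.
#'
#' @param raw a [volume()] in raw units, or a numeric vector/array.
#' @param air_intensity,water_intensity raw intensities of air and water;
#'   must differ.
#' @return same shape as `raw`, in HU (a `volume` if the input was one).
#' @export
scale_to_hu <- function(raw, air_intensity, water_intensity) {
  if (water_intensity == air_intensity)
    stop("degenerate scaling: air and water references are equal")
  hu <- 1000 * (unclass(raw) - air_intensity) / (water_intensity - air_intensity)
  if (inherits(raw, "volume")) vol_like(hu, raw, units = "HU") else hu
}

#' Per-phantom ROI statistics in a calibrated volume
#'
#' Computes the mean and standard deviation of HU over each phantom ROI,
#' together with the per-slice mean HU series used for the slice-profile
#' plots of the calibration workflow.
#'
#' @param volume_hu a [volume()] in HU.
#' @param rois named list (one entry per phantom) of logical arrays the size
#'   of `volume_hu`, or integer voxel-index vectors.
#' @param nominal_md named numeric vector of known phantom mineral densities
#'   (mg/cc), names matching `rois`.
#' @return data.frame with columns `phantom_id`, `nominal_md`, `mean_hu`,
#'   `sd_hu`, `n_voxels`; attribute `"slice_profiles"` holds the per-slice
#'   mean HU series per phantom.
#' @export
phantom_roi_stats <- function(volume_hu, rois, nominal_md) {
  stopifnot(inherits(volume_hu, "volume"), vol_units(volume_hu) == "HU")
  if (is.null(names(rois)) || any(!nzchar(names(rois))))
    stop("`rois` must be a named list")
  if (anyDuplicated(names(rois))) stop("duplicate phantom ids in `rois`")
  missing_md <- setdiff(names(rois), names(nominal_md))
  if (length(missing_md))
    stop("no nominal MD for phantom(s): ", paste(missing_md, collapse = ", "))
  v <- unclass(volume_hu)
  nz <- dim(v)[3]
  idx_list <- lapply(names(rois), function(id) {
    r <- rois[[id]]
    idx <- if (is.logical(r)) which(r) else as.integer(r)
    if (length(idx) == 0L) stop("empty ROI for phantom '", id, "'")
    idx
  })
  names(idx_list) <- names(rois)
  ## disjointness check
  all_idx <- unlist(idx_list, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("phantom ROIs overlap")

  nxy <- prod(dim(v)[1:2])
  out <- lapply(names(rois), function(id) {
    idx <- idx_list[[id]]
    vals <- v[idx]
    data.frame(phantom_id = id,
               nominal_md = unname(nominal_md[id]),
               mean_hu = mean(vals),
               sd_hu = if (length(vals) > 1) stats::sd(vals) else 0,
               n_voxels = length(vals))
  })
  res <- do.call(rbind, out)
  profiles <- lapply(idx_list, function(idx) {
    z <- ((idx - 1L) %/% nxy) + 1L
    means <- tapply(v[idx], z, mean)
    data.frame(slice = as.integer(names(means)), mean_hu = as.numeric(means))
  })
  attr(res, "slice_profiles") <- profiles
  res
}

#' Fit the mineral-density-vs-HU calibration line
#'
#' Ordinary least squares of nominal mineral density on mean phantom HU
#' (MD regressed on HU, matching the direction the calibration is applied).
#' Unweighted by default; `weighted = TRUE` uses inverse-variance weights
#' `n_voxels / sd_hu^2`.
#'
#' @param measurements data.frame as returned by [phantom_roi_stats()]
#'   (needs `phantom_id`, `nominal_md`, `mean_hu`; `sd_hu`/`n_voxels` only
#'   for the weighted option).
#' @param weighted logical; default `FALSE`.
#' @return a [calibration_model()] with residual table and r-squared.
#' @export
fit_calibration <- function(measurements, weighted = FALSE) {
  m <- as.data.frame(measurements)
  req <- c("phantom_id", "nominal_md", "mean_hu")
  if (!all(req %in% names(m)))
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  if (nrow(m) < 2L || length(unique(m$mean_hu)) < 2L)
    stop("rank-deficient calibration: need >= 2 distinct mean HU values")
  w <- if (weighted) {
    if (any(m$sd_hu <= 0)) stop("weighted fit requires positive sd_hu")
    m$n_voxels / m$sd_hu^2
  } else NULL
  fit <- stats::lm(nominal_md ~ mean_hu, data = m, weights = w)
  co <- stats::coef(fit)
  fitted_md <- as.numeric(stats::fitted(fit))
  resid_tab <- data.frame(phantom_id = m$phantom_id, mean_hu = m$mean_hu,
                          nominal_md = m$nominal_md, fitted_md = fitted_md,
                          residual = m$nominal_md - fitted_md)
  ss_res <- sum(resid_tab$residual^2)
  ss_tot <- sum((m$nominal_md - mean(m$nominal_md))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  calibration_model(slope = unname(co["mean_hu"]),
                    intercept = unname(co["(Intercept)"]),
                    r_squared = r2, residuals = resid_tab)
}

#' Convert HU to mineral density
#'
#' Applies `MD = slope * HU + intercept`. Negative mineral densities are
#' preserved (clamping would bias segment means) and flagged through the
#' `"n_negative"` attribute on the result.
#'
#' @param x HU scalar, array, or [volume()] in HU.
#' @param calib a [calibration_model()].
#' @return same shape as `x` in mg/cc, with attribute `n_negative`.
#' @export
md_from_hu <- function(x, calib) {
  stopifnot(inherits(calib, "calibration_model"))
  md <- calib$slope * unclass(x) + calib$intercept
  out <- if (inherits(x, "volume")) vol_like(md, x, units = "mgcc") else md
  attr(out, "n_negative") <- sum(md < 0)
  out
}

#' Convert mineral density to HU (inverse of the calibration line)
#'
#' @param md mg/cc scalar or array.
#' @param calib_truth a [calibration_model()]; slope must be non-zero.
#' @return HU values, exact pre-image of `md` under [md_from_hu()].
#' @export
hu_from_md <- function(md, calib_truth) {
  stopifnot(inherits(calib_truth, "calibration_model"))
  if (calib_truth$slope == 0) stop("invalid calibration: zero slope")
  (unclass(md) - calib_truth$intercept) / calib_truth$slope
}

#' Compare the CT calibration line with the gravimetric (ash) line
#'
#' Fits the ash mineral densities against the same phantom HU values, then
#' evaluates both lines on an HU grid spanning the phantoms, reporting the
#' pointwise residual curve (CT prediction minus ash prediction) and the
#' Pearson correlation of the two lines' predictions over the grid. The
#' correlation of the matched point pairs (CT-predicted vs ash MD at the
#' phantom HUs) is co-reported as `point_correlation`.
#'
#' @param calib fitted [calibration_model()] with a residual table.
#' @param ash_points data.frame with `phantom_id` and `ash_md` (mg/cc);
#'   ids must match phantoms in the fit.
#' @param n_grid number of HU grid points for the residual curve.
#' @return list with `ash_line` (slope, intercept), `residual_curve`
#'   (data.frame `hu`, `ct_md`, `ash_md`, `residual`), `prediction_correlation`
#'   and `point_correlation`.
#' @export
compare_with_gravimetric <- function(calib, ash_points, n_grid = 101L) {
  stopifnot(inherits(calib, "calibration_model"))
  if (is.null(calib$residuals))
    stop("calibration model carries no phantom table; refit with fit_calibration()")
  ash <- as.data.frame(ash_points)
  if (nrow(ash) < 2L) stop("need >= 2 ash points")
  idx <- match(ash$phantom_id, calib$residuals$phantom_id)
  if (anyNA(idx))
    stop("unmatched phantom id(s): ",
         paste(ash$phantom_id[is.na(idx)], collapse = ", "))
  hu <- calib$residuals$mean_hu[idx]
  afit <- stats::lm(ash$ash_md ~ hu)
  a_co <- stats::coef(afit)
  grid <- seq(min(hu), max(hu), length.out = n_grid)
  ct_md <- calib$slope * grid + calib$intercept
  ash_md <- unname(a_co[2]) * grid + unname(a_co[1])
  pred_cor <- if (stats::sd(ct_md) > 0 && stats::sd(ash_md) > 0)
    stats::cor(ct_md, ash_md) else NA_real_
  ct_at_points <- calib$slope * hu + calib$intercept
  pt_cor <- if (stats::sd(ct_at_points) > 0 && stats::sd(ash$ash_md) > 0)
    stats::cor(ct_at_points, ash$ash_md) else NA_real_
  list(ash_line = c(slope = unname(a_co[2]), intercept = unname(a_co[1])),
       residual_curve = data.frame(hu = grid, ct_md = ct_md, ash_md = ash_md,
                                   residual = ct_md - ash_md),
       prediction_correlation = pred_cor,
       point_correlation = pt_cor)
}
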