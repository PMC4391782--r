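#' Default elemental-ratio parameters per tissue class
#'
#' Molar Ca/P and Ca/Zn ratios, and base Ca volume concentration, used by the
#' XRF map generator. Ca concentrations scale the tissue's mineral density by
#' the Ca content of stoichiometric hydroxyapatite (~31.5 mmol/cm3 at
#' 3160 mg/cc). `ca_zn` is `NA` where no Zn signal is emulated. A CSV copy
#' ships in `inst/extdata/xrf_ratio_defaults.csv`.
#'
#' @return data.frame `tissue`, `ca_mmolcc`, `ca_p`, `ca_p_sd`, `ca_zn`,
#'   `ca_zn_sd`.
#' @export
xrf_ratio_defaults <- function() {
  data.frame(
    tissue    = c("dentin", "bone", "cementum", "lesion_zone1",
                  "lesion_zone2", "acellular_cementum", "cellular_cementum",
                  "bone_interface"),
    ca_mmolcc = c(15.3, 11.1, 12.8, 4.5, 6.0, 12.8, 12.8, 11.1),
    ca_p      = c(1.49, 1.68, 1.51, 0.32, 0.46, 1.51, 1.52, 1.68),
    ca_p_sd   = c(0.21, 0.20, 0.22, 0.05, 0.04, 0.13, 0.13, 0.20),
    ca_zn     = c(NA, 2765, 990, NA, NA, 595, 1155, 855),
    ca_zn_sd  = c(NA, 905, 430, NA, NA, 50, 165, 125)
  )
}

#' Alternating band region layout
#'
#' Label matrix of bands perpendicular to the row axis, alternating labels 1
#' and 2 with spatial period `period_px` (each band `period_px / 2` rows
#' wide). Emulates alternating acellular (label 1) / cellular (label 2)
#' cementum increments.
#'
#' @param nrow,ncol raster size.
#' @param period_px full band period in pixels (even).
#' @return integer matrix of labels 1/2.
#' @export
banded_regions <- function(nrow, ncol, period_px = 20L) {
  if (period_px < 2) stop("period must be >= 2 px")
  phase <- ((seq_len(nrow) - 1L) %% period_px) < period_px / 2
  matrix(ifelse(phase, 1L, 2L), nrow, ncol)
}

#' Lesion region layout: severe cap, transition band, normal base
#'
#' Labels 1 (severe lesion, top rows), 2 (adjacent transition), 3 (normal
#' tissue) stacked along the row axis.
#'
#' @param nrow,ncol raster size.
#' @param zone_fracs fractions of rows for zones 1 and 2.
#' @return integer matrix of labels 1/2/3.
#' @export
lesion_regions <- function(nrow, ncol, zone_fracs = c(0.25, 0.25)) {
  n1 <- max(1L, round(zone_fracs[1] * nrow))
  n2 <- max(1L, round(zone_fracs[2] * nrow))
  if (n1 + n2 >= nrow) stop("zone fractions leave no normal tissue")
  lab <- c(rep(1L, n1), rep(2L, n2), rep(3L, nrow - n1 - n2))
  matrix(lab, nrow, ncol)
}

#' Synthesize XRF count maps with known ground truth
#'
#' Forward model: per pixel the Ca volume concentration is the regional base
#' value times a shared mineral-amplitude factor (mean-one Gaussian,
#' coefficient of variation `noise_cv`); P and Zn are derived as Ca divided
#' by the regional ratio times an independent mean-one composition factor, so
#' the mean of the per-pixel ratio field equals the configured ratio. Volume
#' concentrations become area concentrations through the self-absorption
#' effective thickness (the same Beer-Lambert model [thickness_correct()]
#' inverts), then counts through the per-element detector gain, with optional
#' Poisson counting noise.
#'
#' @param regions integer label matrix (from [banded_regions()],
#'   [lesion_regions()], or `matrix(1L, n, m)` for a uniform field).
#' @param params data.frame with one row per region label: `region`,
#'   `ca_mmolcc`, `ca_p`, and optionally `ca_zn` (`NA` = no Zn).
#' @param ctx an [absorption_context()] (thickness scalar or matrix matching
#'   `regions`).
#' @param standards named list of [element_standard()] for Ca, P, Zn.
#' @param pixel_size_um pixel pitch.
#' @param noise_cv coefficient of variation of the mean-one amplitude and
#'   composition factors (0 = deterministic).
#' @param poisson add Poisson counting noise to the count maps.
#' @param thin_limit bypass self-absorption in the forward model (counts
#'   proportional to concentration times geometric thickness).
#' @param seed integer seed; required when `noise_cv > 0` or `poisson`.
#' @return list with `maps` (named list of count [element_map()]s) and
#'   `truth` (region `labels`, per-element true volume-concentration
#'   matrices `conc`, true per-pixel ratio fields `ratio`, `params`,
#'   `ctx`, `seed`).
#' @export
make_xrf_maps <- function(regions, params, ctx = absorption_context(2),
                          standards = default_standards(),
                          pixel_size_um = 1, noise_cv = 0, poisson = FALSE,
                          thin_limit = FALSE, seed = NULL) {
  regions <- matrix(as.integer(regions), nrow(regions), ncol(regions))
  p <- as.data.frame(params)
  req <- c("region", "ca_mmolcc", "ca_p")
  if (!all(req %in% names(p)))
    stop("params must have columns: ", paste(req, collapse = ", "))
  if (!"ca_zn" %in% names(p)) p$ca_zn <- NA_real_
  ids <- sort(unique(as.integer(regions)))
  if (!all(ids %in% p$region))
    stop("params missing region(s): ",
         paste(setdiff(ids, p$region), collapse = ", "))
  if (any(p$ca_mmolcc < 0, na.rm = TRUE) || any(p$ca_p <= 0, na.rm = TRUE))
    stop("concentrations must be non-negative and ratios positive")
  t <- ctx$thickness_um
  if (any(t <= 0)) stop("thickness must be positive everywhere")
  stochastic <- noise_cv > 0 || poisson
  if (stochastic && is.null(seed))
    stop("`seed` is required for stochastic synthesis")
  if (!is.null(seed)) set.seed(seed)

  d <- dim(regions)
  npx <- prod(d)
  ridx <- match(as.integer(regions), p$region)
  mean_one <- function() {
    if (noise_cv > 0) 1 + stats::rnorm(npx, sd = noise_cv) else rep(1, npx)
  }
  ca <- p$ca_mmolcc[ridx] * mean_one()
  rp <- p$ca_p[ridx] * mean_one()
  phos <- ca / rp
  zn_ratio <- p$ca_zn[ridx]
  rz <- ifelse(is.na(zn_ratio), NA_real_, zn_ratio * mean_one())
  zn <- ifelse(is.na(rz), 0, ca / rz)

  conc <- list(Ca = matrix(ca, d[1], d[2]),
               P = matrix(phos, d[1], d[2]),
               Zn = matrix(zn, d[1], d[2]))
  maps <- lapply(names(conc), function(el) {
    teff_um <- if (thin_limit) t else effective_thickness(ctx, el)
    area <- conc[[el]] * (teff_um * 1e-4)     # mmol/cm2
    counts <- area * standards[[el]]$gain
    if (poisson) counts <- matrix(stats::rpois(npx, lambda = counts),
                                  d[1], d[2])
    element_map(counts, element = el, units = "counts",
                pixel_size_um = pixel_size_um)
  })
  names(maps) <- names(conc)
  list(maps = maps,
       truth = list(labels = regions, conc = conc,
                    ratio = list(ca_p = matrix(ca / phos, d[1], d[2]),
                                 ca_zn = matrix(ifelse(zn > 0, ca / zn, NA),
                                                d[1], d[2])),
                    params = p, ctx = ctx, seed = seed))
}
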