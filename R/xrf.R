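#' Elemental raster map
#'
#' A 2D per-element raster with tracked units. Arithmetic between maps of
#' different units is rejected by [map_math()]; unit changes happen only
#' through [calibrate_counts()] (counts -> mmol/cm2) and
#' [thickness_correct()] (mmol/cm2 -> mmol/cm3).
#'
#' @param data numeric matrix.
#' @param element element symbol, e.g. `"Ca"`, `"P"`, `"Zn"`.
#' @param units one of `"counts"`, `"mmol_cm2"`, `"mmol_cm3"`.
#' @param pixel_size_um pixel pitch, micrometres.
#' @return object of class `element_map`.
#' @export
element_map <- function(data, element, units = c("counts", "mmol_cm2",
                                                 "mmol_cm3"),
                        pixel_size_um = 1) {
  units <- match.arg(units)
  if (!is.matrix(data)) stop("`data` must be a matrix")
  structure(data, element = element, units = units,
            pixel_size_um = pixel_size_um,
            class = c("element_map", "matrix", "array"))
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("<element_map> %s, %d x %d px, %.3g um/px, units: %s\n",
              attr(x, "element"), nrow(x), ncol(x),
              attr(x, "pixel_size_um"), attr(x, "units")))
  invisible(x)
}

map_units <- function(x) attr(x, "units") %||% stop("map has no units")
map_element <- function(x) attr(x, "element")

map_like <- function(data, template, units = map_units(template),
                     element = map_element(template)) {
  element_map(data, element = element, units = units,
              pixel_size_um = attr(template, "pixel_size_um"))
}

#' Thin-film elemental standard
#'
#' Detector gain per element derived from thin-film reference standards.
#'
#' @param element element symbol.
#' @param gain_counts_per_mmolcm2 detector counts per mmol/cm2; positive.
#' @param line_energy_kev fluorescence line energy, keV; positive.
#' @param yield fluorescence yield (informational).
#' @return object of class `element_standard`.
#' @export
element_standard <- function(element, gain_counts_per_mmolcm2,
                             line_energy_kev, yield = NA_real_) {
  if (gain_counts_per_mmolcm2 <= 0) stop("gain must be positive")
  if (line_energy_kev <= 0) stop("line energy must be positive")
  structure(list(element = element,
                 gain = gain_counts_per_mmolcm2,
                 line_energy_kev = line_energy_kev, yield = yield),
            class = "element_standard")
}

#' Default element standards table
#'
#' Synthetic detector gains and K-alpha line energies for Ca, P and Zn used
#' by the map generator; in real use these come from the measured thin-film
#' standards. A CSV template ships in `inst/extdata/element_standards.csv`.
#'
#' @return named list of [element_standard()].
#' @export
default_standards <- function() {
  list(Ca = element_standard("Ca", 2000, 3.69),
       P  = element_standard("P", 800, 2.01),
       Zn = element_standard("Zn", 5000, 8.64))
}

#' Absorption context for thickness / self-absorption correction
#'
#' Single-layer uniform-matrix Beer-Lambert geometry. Absorption lengths
#' (the 1/e attenuation depth) are user inputs per energy: one at the
#' incident energy and one per element at its fluorescence line energy.
#'
#' @param thickness_um specimen thickness, micrometres (scalar or matrix);
#'   must be positive wherever valid.
#' @param absorption_length_in_um absorption length at the incident energy.
#' @param absorption_length_f_um named numeric vector, one entry per element,
#'   absorption length at that element's fluorescence energy.
#' @param incident_energy_kev incident beam energy (default 10).
#' @param incidence_deg,takeoff_deg beam incidence and detector take-off
#'   angles from the specimen surface, in (0, 90].
#' @return object of class `absorption_context`.
#' @export
absorption_context <- function(thickness_um,
                               absorption_length_in_um = 45,
                               absorption_length_f_um = c(Ca = 9, P = 3,
                                                          Zn = 60),
                               incident_energy_kev = 10,
                               incidence_deg = 45, takeoff_deg = 45) {
  if (any(thickness_um <= 0, na.rm = TRUE))
    stop("thickness must be positive")
  if (absorption_length_in_um <= 0 || any(absorption_length_f_um <= 0))
    stop("absorption lengths must be positive")
  if (incidence_deg <= 0 || incidence_deg > 90 ||
      takeoff_deg <= 0 || takeoff_deg > 90)
    stop("angles must lie in (0, 90]")
  structure(list(thickness_um = thickness_um,
                 absorption_length_in_um = absorption_length_in_um,
                 absorption_length_f_um = absorption_length_f_um,
                 incident_energy_kev = incident_energy_kev,
                 incidence_deg = incidence_deg, takeoff_deg = takeoff_deg),
            class = "absorption_context")
}

## total effective attenuation coefficient along the in/out path, per um
mu_total <- function(ctx, element) {
  lf <- ctx$absorption_length_f_um[[element]]
  if (is.null(lf)) stop("no fluorescence absorption length for ", element)
  (1 / ctx$absorption_length_in_um) / sin(ctx$incidence_deg * pi / 180) +
    (1 / lf) / sin(ctx$takeoff_deg * pi / 180)
}

#' Self-absorption effective thickness
#'
#' `t_eff = (1 - exp(-mu_tot * t)) / mu_tot`, with `mu_tot` the summed
#' path-weighted attenuation of the incident beam and of the element's
#' fluorescence photons. `t_eff <= t` always; in the thin-sample limit
#' (`mu_tot * t -> 0`) it converges to `t`, and it is bounded above by
#' `1 / mu_tot`.
#'
#' @param ctx an [absorption_context()].
#' @param element element symbol (selects the fluorescence absorption
#'   length).
#' @return effective thickness in micrometres; scalar or matrix matching
#'   `ctx$thickness_um`.
#' @export
effective_thickness <- function(ctx, element) {
  stopifnot(inherits(ctx, "absorption_context"))
  mu <- mu_total(ctx, element)
  t <- ctx$thickness_um
  if (mu * max(t) < 1e-12) return(t)
  (1 - exp(-mu * t)) / mu
}

#' Convert raw XRF counts to area concentration
#'
#' Divides counts by the element's standard-derived detector gain;
#' units become mmol/cm2.
#'
#' @param raw an [element_map()] in counts.
#' @param std matching [element_standard()].
#' @return [element_map()] in mmol/cm2.
#' @export
calibrate_counts <- function(raw, std) {
  stopifnot(inherits(raw, "element_map"), inherits(std, "element_standard"))
  if (map_units(raw) != "counts")
    stop("calibrate_counts expects a map in counts, got ", map_units(raw))
  if (!identical(map_element(raw), std$element))
    stop("element mismatch: map is ", map_element(raw), ", standard is ",
         std$element)
  map_like(unclass(raw) / std$gain, raw, units = "mmol_cm2")
}

#' Thickness / self-absorption correction: area to volume concentration
#'
#' Divides the area concentration by the self-absorption effective thickness
#' (in cm), inverting the single-layer Beer-Lambert forward model. Pixels
#' with non-positive thickness are set `NA` and flagged through the
#' `"invalid"` attribute (a logical matrix).
#'
#' @param area an [element_map()] in mmol/cm2.
#' @param ctx an [absorption_context()]; `thickness_um` scalar or a matrix
#'   aligned with the raster.
#' @param thin_limit if `TRUE`, divide by the geometric thickness instead
#'   (no self-absorption).
#' @return [element_map()] in mmol/cm3 with attribute `invalid`.
#' @export
thickness_correct <- function(area, ctx, thin_limit = FALSE) {
  stopifnot(inherits(area, "element_map"))
  if (map_units(area) != "mmol_cm2")
    stop("thickness_correct expects mmol/cm2, got ", map_units(area))
  t <- ctx$thickness_um
  if (is.matrix(t) && !all(dim(t) == dim(area)))
    stop("thickness map not aligned with raster")
  bad <- !(t > 0)
  tt <- ifelse(bad, NA_real_, t)
  ctx2 <- ctx; ctx2$thickness_um <- ifelse(bad, 1, tt)  # guard for t_eff
  teff_um <- if (thin_limit) tt
             else ifelse(bad, NA_real_,
                         effective_thickness(ctx2, map_element(area)))
  conc <- unclass(area) / (teff_um * 1e-4)
  if (!is.matrix(conc)) conc <- matrix(conc, nrow(area), ncol(area))
  conc[if (is.matrix(bad)) bad else rep(bad, length.out = length(conc))] <- NA_real_
  out <- map_like(conc, area, units = "mmol_cm3")
  attr(out, "invalid") <- if (is.matrix(bad)) bad
                          else matrix(bad, nrow(area), ncol(area))
  out
}

#' Write an element map as 32-bit float TIFF plus JSON sidecar
#'
#' @param map an [element_map()].
#' @param path path without extension.
#' @param meta extra sidecar fields.
#' @return `path`, invisibly.
#' @export
write_element_map <- function(map, path, meta = list()) {
  stopifnot(inherits(map, "element_map"))
  m <- unclass(map)
  vmin <- min(m, na.rm = TRUE); vmax <- max(m, na.rm = TRUE)
  rng <- if (vmax > vmin) vmax - vmin else 1
  norm <- (m - vmin) / rng
  norm[is.na(norm)] <- 0
  tiff::writeTIFF(norm, paste0(path, ".tiff"), bits.per.sample = 32L)
  jsonlite::write_json(
    c(list(element = map_element(map), units = map_units(map),
           pixel_size_um = attr(map, "pixel_size_um"), dim = dim(m),
           value_min = vmin, value_max = vmax), meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an element map written by [write_element_map()]
#' @param path path without extension.
#' @return an [element_map()].
#' @export
read_element_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(paste0(path, ".tiff"))
  rng <- side$value_max - side$value_min
  if (rng <= 0) rng <- 1
  element_map(m * rng + side$value_min, element = side$element,
              units = side$units, pixel_size_um = side$pixel_size_um)
}
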