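#' Gradient magnitude of a volume
#'
#' Euclidean norm of the per-axis central-difference gradient (exact on
#' linear ramps). Borders are handled by edge replication, so one-sided
#' differences at the faces are halved.
#'
#' @param vol a [volume()] or numeric 2D/3D array.
#' @return gradient-magnitude array of the same shape (a `volume` with units
#'   preserved per voxel step if the input was one).
#' @export
gradient_magnitude <- function(vol) {
  a <- unclass(vol)
  d <- dim(a)
  if (is.null(d)) stop("input must be an array")
  if (any(d < 2) && sum(d > 1) == 0) stop("need >= 2 voxels along an axis")
  g2 <- array(0, d)
  for (ax in seq_along(d)) {
    n <- d[ax]
    if (n < 2) next
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    idx_p <- idx_m <- vector("list", length(d))
    for (k in seq_along(d)) idx_p[[k]] <- idx_m[[k]] <- quote(expr = )
    idx_p[[ax]] <- ip; idx_m[[ax]] <- im
    shift_p <- do.call(`[`, c(list(a), idx_p, list(drop = FALSE)))
    shift_m <- do.call(`[`, c(list(a), idx_m, list(drop = FALSE)))
    g2 <- g2 + ((shift_p - shift_m) / 2)^2
  }
  out <- sqrt(g2)
  if (inherits(vol, "volume")) vol_like(out, vol) else out
}

#' Joint intensity/gradient-magnitude 2D histogram
#'
#' The diagnostic view used to seed the watershed: material phases appear as
#' high-count columns at low gradient, and interfaces between two materials
#' appear as arches connecting the columns at elevated gradient.
#'
#' @param vol intensity volume (HU) or array.
#' @param gradmag matching gradient-magnitude array; computed with
#'   [gradient_magnitude()] if `NULL`.
#' @param bins integer 2-vector: number of intensity and gradient bins.
#' @param mask optional logical array restricting the histogram.
#' @return object of class `histogram2d`: list with `counts` (intensity x
#'   gradient matrix), `intensity_edges`, `gradient_edges`, `n`.
#' @export
histogram2d <- function(vol, gradmag = NULL, bins = c(128L, 128L),
                        mask = NULL) {
  v <- as.numeric(unclass(vol))
  if (is.null(gradmag)) gradmag <- gradient_magnitude(vol)
  g <- as.numeric(unclass(gradmag))
  if (length(v) != length(g)) stop("volume and gradient shapes differ")
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    if (!any(keep)) stop("mask leaves no voxels")
    v <- v[keep]; g <- g[keep]
  }
  bin_edges <- function(x, nb) {
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = nb + 1L)
  }
  ie <- bin_edges(v, bins[1]); ge <- bin_edges(g, bins[2])
  bi <- findInterval(v, ie, rightmost.closed = TRUE, all.inside = TRUE)
  bg <- findInterval(g, ge, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1], bins[2])
  tab <- table(factor(bi, levels = seq_len(bins[1])),
               factor(bg, levels = seq_len(bins[2])))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, intensity_edges = ie, gradient_edges = ge,
                 n = length(v)),
            class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf("<histogram2d> %d x %d bins, %d voxels\n",
              nrow(x$counts), ncol(x$counts), x$n))
  invisible(x)
}

#' Seed locus: a rectangle in the (intensity, gradient) histogram plane
#'
#' Voxels whose (intensity, gradient-magnitude) pair falls inside the box
#' become the initial markers of one watershed region.
#'
#' @param locus_id positive integer; becomes the segment label.
#' @param intensity,gradient numeric `c(lo, hi)` ranges, `lo < hi`.
#' @param tissue optional expected tissue name.
#' @return object of class `seed_locus`.
#' @export
seed_locus <- function(locus_id, intensity, gradient, tissue = NA_character_) {
  if (intensity[1] >= intensity[2] || gradient[1] >= gradient[2])
    stop("locus ranges must satisfy lo < hi")
  structure(list(locus_id = as.integer(locus_id),
                 intensity = as.numeric(intensity),
                 gradient = as.numeric(gradient), tissue = tissue),
            class = "seed_locus")
}

loci_overlap <- function(a, b) {
  a$intensity[1] < b$intensity[2] && b$intensity[1] < a$intensity[2] &&
    a$gradient[1] < b$gradient[2] && b$gradient[1] < a$gradient[2]
}

#' Select watershed seed loci from a 2D histogram
#'
#' Manual mode validates user-supplied boxes (pairwise disjoint in the
#' histogram plane). Auto mode restricts to the low-gradient band (gradient
#' below the `gradient_quantile` of the gradient marginal), finds local
#' maxima of the band's intensity histogram separated by at least
#' `min_separation_bins`, and returns one locus per peak. Peak boxes span
#' `box_halfwidth_bins` intensity bins either side of the peak, clipped at
#' midpoints between adjacent peaks.
#'
#' @param hist a [histogram2d()].
#' @param mode `"auto"` or `"manual"`.
#' @param boxes list of [seed_locus()] (manual mode).
#' @param gradient_quantile low-gradient band cut, in (0, 1].
#' @param min_separation_bins minimum intensity-bin distance between peaks.
#' @param peak_frac minimum peak height as a fraction of the tallest peak.
#' @param box_halfwidth_bins half-width of each locus box in intensity bins.
#' @return list of [seed_locus()], ids 1..k in increasing intensity order.
#' @export
select_seed_loci <- function(hist, mode = c("auto", "manual"), boxes = NULL,
                             gradient_quantile = 0.5,
                             min_separation_bins = 8L, peak_frac = 0.05,
                             box_halfwidth_bins = 3L) {
  mode <- match.arg(mode)
  stopifnot(inherits(hist, "histogram2d"))
  if (mode == "manual") {
    if (is.null(boxes) || !length(boxes)) stop("manual mode needs boxes")
    for (i in seq_along(boxes)) for (j in seq_len(i - 1L))
      if (loci_overlap(boxes[[i]], boxes[[j]]))
        stop("loci ", boxes[[j]]$locus_id, " and ", boxes[[i]]$locus_id,
             " overlap in the histogram plane")
    return(boxes)
  }
  counts <- hist$counts
  gmarg <- colSums(counts)
  total <- sum(gmarg)
  if (total == 0) stop("empty histogram")
  jmax <- which(cumsum(gmarg) / total >= gradient_quantile)[1]
  band <- rowSums(counts[, seq_len(jmax), drop = FALSE])
  ## light smoothing stabilizes peak detection against count noise
  sm <- stats::filter(band, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- band[is.na(sm)]
  sm <- as.numeric(sm)
  nb_int <- length(sm)
  ## candidates: local maxima within a +/- min_separation window
  is_peak <- vapply(seq_len(nb_int), function(b) {
    win <- max(1L, b - min_separation_bins):min(nb_int, b + min_separation_bins)
    sm[b] > 0 && sm[b] == max(sm[win]) && b == win[which.max(sm[win])]
  }, logical(1))
  cand <- which(is_peak & sm >= peak_frac * max(sm))
  peaks <- integer(0)
  for (b in cand[order(sm[cand], decreasing = TRUE)]) {
    if (!length(peaks) || all(abs(peaks - b) >= min_separation_bins))
      peaks <- c(peaks, b)
  }
  if (!length(peaks))
    stop("no histogram peaks found; try more bins or a lower peak_frac")
  peaks <- sort(peaks)
  ie <- hist$intensity_edges
  glo <- hist$gradient_edges[1]
  ghi <- hist$gradient_edges[jmax + 1L]
  nb <- length(ie) - 1L
  loci <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    lo_bin <- max(1L, peaks[i] - box_halfwidth_bins)
    hi_bin <- min(nb, peaks[i] + box_halfwidth_bins)
    if (i > 1L) lo_bin <- max(lo_bin, floor((peaks[i - 1] + peaks[i]) / 2) + 1L)
    if (i < length(peaks))
      hi_bin <- min(hi_bin, floor((peaks[i] + peaks[i + 1]) / 2))
    loci[[i]] <- seed_locus(i, intensity = c(ie[lo_bin], ie[hi_bin + 1L]),
                            gradient = c(glo, ghi))
  }
  loci
}

#' Marker-based watershed segmentation
#'
#' Floods the gradient-magnitude landscape from the locus markers (voxels
#' whose intensity and gradient fall inside a locus box) using Meyer's
#' priority-flood with 6-connectivity. Every masked voxel receives exactly
#' one label; labels follow locus ids. Flooding order is deterministic:
#' queue ordered by (gradient value, linear voxel index), a voxel keeping the
#' label it is first reached with.
#'
#' @param vol intensity volume (HU).
#' @param loci list of [seed_locus()], or a single locus.
#' @param mask optional logical array; unmasked voxels stay 0.
#' @param gradmag optional precomputed gradient magnitude.
#' @return object of class `label_map`: integer array of segment labels with
#'   attributes `loci` and `voxel_size_um`.
#' @export
watershed_segment <- function(vol, loci, mask = NULL, gradmag = NULL) {
  if (inherits(loci, "seed_locus")) loci <- list(loci)
  if (!length(loci)) stop("need at least one seed locus")
  a <- unclass(vol)
  d <- dim(a)
  if (length(d) == 2L) { a <- array(a, c(d, 1L)); d <- dim(a) }
  if (is.null(gradmag)) gradmag <- gradient_magnitude(a)
  g <- unclass(gradmag)
  if (length(dim(g)) == 2L) g <- array(g, dim(a))
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- array(as.logical(mask), d)

  markers <- array(0L, d)
  for (lc in loci) {
    inside <- a >= lc$intensity[1] & a <= lc$intensity[2] &
      g >= lc$gradient[1] & g <= lc$gradient[2] & mask
    if (!any(inside))
      stop("locus ", lc$locus_id, " has no marker voxels")
    markers[inside & markers == 0L] <- lc$locus_id
  }
  out <- watershed_flood_core(g, markers, mask)
  structure(out,
            loci = loci,
            voxel_size_um = if (inherits(vol, "volume")) vol_voxel(vol)
                            else NA_real_,
            class = c("label_map", "array"))
}

## deterministic priority-flood core (C++); grad/markers/mask are 3D arrays
watershed_flood_core <- function(grad, markers, mask = NULL) {
  d <- dim(grad)
  if (length(d) == 2L) d <- c(d, 1L)
  if (is.null(mask)) mask <- rep(TRUE, prod(d))
  lab <- .watershed_flood(as.numeric(grad), as.integer(markers),
                          as.logical(mask), as.integer(d))
  array(lab, d)
}

#' Per-segment mineral statistics
#'
#' For every non-empty label: voxel count, physical volume, HU mean/sd, and
#' (given a calibration) mineral-density mean/sd/range. For an affine HU-to-MD
#' map the MD mean equals the converted HU mean and the MD sd equals
#' `|slope| * sd_hu`; the range converts the HU extremes.
#'
#' @param labels a `label_map` (or integer array); label 0 is background.
#' @param volume_hu matching [volume()] in HU.
#' @param calib optional [calibration_model()].
#' @param voxel_size_um voxel size; defaults to the volume's.
#' @return data.frame with one row per label: `label`, `n_voxels`,
#'   `volume_mm3`, `mean_hu`, `sd_hu`, `hu_min`, `hu_max`, and with `calib`
#'   also `mean_md`, `sd_md`, `md_min`, `md_max`.
#' @export
segment_stats <- function(labels, volume_hu, calib = NULL,
                          voxel_size_um = NULL) {
  lab <- as.integer(unclass(labels))
  v <- as.numeric(unclass(volume_hu))
  if (length(lab) != length(v)) stop("labels and volume shapes differ")
  if (is.null(voxel_size_um))
    voxel_size_um <- if (inherits(volume_hu, "volume")) vol_voxel(volume_hu)
                     else attr(labels, "voxel_size_um")
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    warning("no labeled voxels")
    return(data.frame())
  }
  rows <- lapply(ids, function(id) {
    vals <- v[lab == id]
    data.frame(label = id, n_voxels = length(vals),
               volume_mm3 = length(vals) * (voxel_size_um * 1e-3)^3,
               mean_hu = mean(vals),
               sd_hu = if (length(vals) > 1) stats::sd(vals) else 0,
               hu_min = min(vals), hu_max = max(vals))
  })
  res <- do.call(rbind, rows)
  if (!is.null(calib)) {
    res$mean_md <- calib$slope * res$mean_hu + calib$intercept
    res$sd_md <- abs(calib$slope) * res$sd_hu
    lo <- calib$slope * res$hu_min + calib$intercept
    hi <- calib$slope * res$hu_max + calib$intercept
    res$md_min <- pmin(lo, hi)
    res$md_max <- pmax(lo, hi)
  }
  res
}

#' Per-slice mean intensity profile through an ROI
#'
#' The slice-wise mineral gradient view: mean HU (optionally converted to
#' mineral density) of the ROI voxels in each slice along an axis.
#'
#' @param volume_hu a [volume()] in HU or 3D array.
#' @param roi optional logical array; default whole volume.
#' @param axis slice axis (default 3, the z axis).
#' @param calib optional [calibration_model()] to co-report MD.
#' @return data.frame `slice`, `mean_hu` (and `mean_md` with `calib`),
#'   covering the slices the ROI intersects.
#' @export
slice_profile <- function(volume_hu, roi = NULL, axis = 3L, calib = NULL) {
  a <- unclass(volume_hu)
  d <- dim(a)
  if (is.null(roi)) roi <- array(TRUE, d)
  sl <- slice.index(a, axis)
  keep <- as.logical(roi)
  if (!any(keep)) stop("empty ROI")
  means <- tapply(a[keep], sl[keep], mean)
  out <- data.frame(slice = as.integer(names(means)),
                    mean_hu = as.numeric(means))
  span <- range(out$slice)
  if (nrow(out) != diff(span) + 1L)
    stop("ROI does not intersect every slice in its span")
  if (!is.null(calib)) out$mean_md <- calib$slope * out$mean_hu + calib$intercept
  out
}

#' Default dentin-zone HU cut-offs
#'
#' Hypomineralized 3545-13475 HU, near normal 13755-14740 HU,
#' hypermineralized above 15000 HU (air = 0 / water = 1000 convention).
#'
#' @return named list of `c(lo, hi)` HU intervals.
#' @export
dentin_zone_cutoffs <- function() {
  list(hypomineralized = c(3545, 13475),
       near_normal = c(13755, 14740),
       hypermineralized = c(15000, Inf))
}

#' Classify dentin segments into mineralization zones by mean HU
#'
#' Segments whose mean HU falls in a gap between the cut-off intervals are
#' flagged `"unclassified"`.
#'
#' @param stats data.frame from [segment_stats()] (needs `mean_hu`).
#' @param cutoffs named list of HU intervals, ordered and non-overlapping;
#'   default [dentin_zone_cutoffs()].
#' @return `stats` with a `zone` column appended.
#' @export
classify_dentin_zones <- function(stats, cutoffs = dentin_zone_cutoffs()) {
  los <- vapply(cutoffs, `[`, numeric(1), 1)
  his <- vapply(cutoffs, `[`, numeric(1), 2)
  if (is.unsorted(los) || any(his[-length(his)] > los[-1]))
    stop("cut-off intervals must be ordered and non-overlapping")
  ## open-ended intervals (hi = Inf) are strictly above their threshold
  zone <- vapply(stats$mean_hu, function(h) {
    hit <- which(ifelse(is.finite(his), h >= los & h <= his, h > los))
    if (length(hit)) names(cutoffs)[hit[1]] else "unclassified"
  }, character(1))
  stats$zone <- zone
  stats
}

#' Dice overlap between a segmentation and ground-truth labels
#'
#' Each predicted label is matched to the truth label it overlaps most;
#' Dice = 2|A n B| / (|A| + |B|) is reported per truth region.
#'
#' @param labels predicted integer labels (0 = background/unmasked).
#' @param truth ground-truth integer labels of the same shape.
#' @return named numeric vector of Dice coefficients, one per truth label.
#' @export
dice_coefficient <- function(labels, truth) {
  lab <- as.integer(unclass(labels)); tr <- as.integer(unclass(truth))
  stopifnot(length(lab) == length(tr))
  tids <- sort(unique(tr[tr > 0L]))
  lids <- sort(unique(lab[lab > 0L]))
  ## match each predicted label to its majority truth label
  map <- vapply(lids, function(l) {
    ov <- tabulate(tr[lab == l & tr > 0L], nbins = max(tids))
    if (all(ov == 0)) NA_integer_ else which.max(ov)
  }, integer(1))
  out <- vapply(tids, function(t) {
    pred <- lab %in% lids[!is.na(map) & map == t]
    tru <- tr == t
    2 * sum(pred & tru) / (sum(pred) + sum(tru))
  }, numeric(1))
  names(out) <- paste0("region_", tids)
  out
}
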