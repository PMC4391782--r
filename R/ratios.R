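#' Pixelwise arithmetic between element maps
#'
#' Addition, subtraction and multiplication require identical units and
#' raster geometry and return an [element_map()]. Division returns a
#' `ratio_map`: a dimensionless per-pixel ratio raster carrying a validity
#' mask (pixels whose denominator is at or below `floor` are invalid and
#' excluded from all downstream statistics) plus the numerator and
#' denominator rasters, so both ratio-averaging conventions stay available.
#'
#' @param a,b [element_map()]s with matching geometry.
#' @param op one of `"/"`, `"-"`, `"+"`, `"*"`.
#' @param floor detection floor for the denominator of a division.
#' @return a `ratio_map` for `"/"`, otherwise an [element_map()].
#' @export
map_math <- function(a, b, op = c("/", "-", "+", "*"), floor = 0) {
  op <- match.arg(op)
  stopifnot(inherits(a, "element_map"), inherits(b, "element_map"))
  if (!all(dim(a) == dim(b)) ||
      !isTRUE(all.equal(attr(a, "pixel_size_um"), attr(b, "pixel_size_um"))))
    stop("raster geometry mismatch")
  if (map_units(a) != map_units(b))
    stop("unit mismatch: ", map_units(a), " vs ", map_units(b))
  ma <- unclass(a); mb <- unclass(b)
  if (op == "/") {
    valid <- is.finite(ma) & is.finite(mb) & mb > floor
    r <- ifelse(valid, ma / mb, NA_real_)
    return(structure(r,
                     numerator = map_element(a), denominator = map_element(b),
                     num_data = ma, den_data = mb, valid = valid,
                     pixel_size_um = attr(a, "pixel_size_um"),
                     class = c("ratio_map", "matrix", "array")))
  }
  res <- switch(op, "-" = ma - mb, "+" = ma + mb, "*" = ma * mb)
  map_like(res, a, units = map_units(a),
           element = paste0(map_element(a), op, map_element(b)))
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf("<ratio_map> %s/%s, %d x %d px, %d valid\n",
              attr(x, "numerator"), attr(x, "denominator"),
              nrow(x), ncol(x), sum(attr(x, "valid"))))
  invisible(x)
}

#' Masked statistics of a ratio or element map
#'
#' Mean and standard deviation over the valid masked pixels. For ratio maps
#' two conventions are available: the default `mean_of_ratios` averages the
#' per-pixel ratios; `ratio_of_means` divides the masked mean numerator by
#' the masked mean denominator (sd still reported from the per-pixel ratios).
#'
#' @param x a `ratio_map` from [map_math()] or an [element_map()].
#' @param mask optional logical matrix.
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param roi name recorded in the output.
#' @return data.frame `roi`, `method`, `mean`, `sd`, `n_pixels`.
#' @export
masked_stats <- function(x, mask = NULL,
                         method = c("mean_of_ratios", "ratio_of_means"),
                         roi = "roi") {
  method <- match.arg(method)
  m <- unclass(x)
  valid <- attr(x, "valid") %||% is.finite(m)
  if (!is.null(mask)) valid <- valid & as.logical(mask)
  n <- sum(valid)
  if (n == 0L) stop("mask leaves no valid pixels")
  vals <- m[valid]
  mean_val <- if (method == "ratio_of_means" && inherits(x, "ratio_map")) {
    mean(attr(x, "num_data")[valid]) / mean(attr(x, "den_data")[valid])
  } else mean(vals)
  data.frame(roi = roi, method = method, mean = mean_val,
             sd = if (n > 1) stats::sd(vals) else 0, n_pixels = n)
}

#' Joint density (correlation) plot of two element maps
#'
#' 2D histogram of the two maps over the masked valid pixels, with peak
#' detection: local maxima at least `peak_min_sep_bins` apart (Chebyshev
#' distance) each holding at least `peak_min_frac` of the masked counts.
#' Two or more peaks flag the mask as holding localized, distinct
#' concentration zones; one peak indicates a single spread population.
#'
#' @param a,b [element_map()]s of matching geometry.
#' @param mask optional logical matrix.
#' @param bins bins per axis.
#' @param peak_min_frac minimum per-bin count as a fraction of masked pixels.
#' @param peak_min_sep_bins minimum bin separation between peaks.
#' @return list: `counts` matrix, `a_edges`, `b_edges`,
#'   `peaks` (data.frame `a`, `b`, `count`), `localized`, `n`.
#' @export
density_plot <- function(a, b, mask = NULL, bins = 64L,
                         peak_min_frac = 0.05, peak_min_sep_bins = 3L) {
  stopifnot(inherits(a, "element_map"), inherits(b, "element_map"))
  if (!all(dim(a) == dim(b))) stop("raster geometry mismatch")
  va <- as.numeric(unclass(a)); vb <- as.numeric(unclass(b))
  keep <- is.finite(va) & is.finite(vb)
  if (!is.null(mask)) keep <- keep & as.logical(mask)
  if (!any(keep)) stop("mask leaves no valid pixels")
  va <- va[keep]; vb <- vb[keep]
  edges <- function(x, nb) {
    r <- range(x); if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = nb + 1L)
  }
  ae <- edges(va, bins); be <- edges(vb, bins)
  ia <- findInterval(va, ae, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(vb, be, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ia, levels = seq_len(bins)),
               factor(ib, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  thr <- peak_min_frac * length(va)
  cand <- which(counts >= thr, arr.ind = TRUE)
  peaks <- NULL
  if (nrow(cand)) {
    ord <- order(counts[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    sel <- matrix(0L, 0, 2)
    for (k in seq_len(nrow(cand))) {
      pt <- cand[k, ]
      if (!nrow(sel) ||
          all(pmax(abs(sel[, 1] - pt[1]), abs(sel[, 2] - pt[2])) >=
              peak_min_sep_bins))
        sel <- rbind(sel, pt)
    }
    mids <- function(e) (e[-1] + e[-length(e)]) / 2
    peaks <- data.frame(a = mids(ae)[sel[, 1]], b = mids(be)[sel[, 2]],
                        count = counts[sel])
  } else {
    peaks <- data.frame(a = numeric(), b = numeric(), count = integer())
  }
  list(counts = counts, a_edges = ae, b_edges = be, peaks = peaks,
       localized = nrow(peaks) >= 2L, n = length(va))
}

#' Two-channel color composite of two element maps
#'
#' Each map is normalized to \[0, 1\] by percentile clipping, then composited
#' into an RGB image: pixels dominated by `a` show `a`'s color, pixels
#' dominated by `b` show `b`'s, and overlap mixes the two. A pure view: the
#' input data are not modified and statistics are unaffected by the
#' normalization.
#'
#' @param a,b [element_map()]s of matching geometry.
#' @param colors length-2 vector of R colors for `a` and `b`
#'   (default blue/red).
#' @param probs percentile clip range for normalization.
#' @return numeric array `nrow x ncol x 3` in \[0, 1\] with attribute
#'   `normalization` recording the clip values per channel.
#' @export
bicolor_overlay <- function(a, b, colors = c("blue", "red"),
                            probs = c(0.01, 0.99)) {
  stopifnot(inherits(a, "element_map"), inherits(b, "element_map"))
  if (!all(dim(a) == dim(b))) stop("raster geometry mismatch")
  norm <- function(m) {
    v <- unclass(m)
    q <- stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
    if (q[2] <= q[1]) q[2] <- q[1] + 1
    pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  na <- norm(a); nb <- norm(b)
  ca <- grDevices::col2rgb(colors[1]) / 255
  cb <- grDevices::col2rgb(colors[2]) / 255
  out <- array(0, c(dim(a), 3L))
  for (ch in 1:3) out[, , ch] <- pmin(na * ca[ch] + nb * cb[ch], 1)
  qa <- stats::quantile(unclass(a), probs, na.rm = TRUE, names = FALSE)
  qb <- stats::quantile(unclass(b), probs, na.rm = TRUE, names = FALSE)
  attr(out, "normalization") <- list(a = qa, b = qb, probs = probs,
                                     colors = colors)
  out
}

#' Line profile through a map
#'
#' Samples the raster along a polyline at pixel pitch using bilinear
#' interpolation, averaging across `width_px` perpendicular offsets.
#' Distances are reported in millimetres from the pixel size.
#'
#' @param map an [element_map()], `ratio_map`, or plain matrix with a
#'   `pixel_size_um` attribute.
#' @param polyline two-column matrix of (row, col) vertices in pixel
#'   coordinates (1-based).
#' @param width_px profile width in pixels (averaged perpendicular to the
#'   local direction).
#' @return data.frame `distance_mm`, `value`.
#' @export
line_profile <- function(map, polyline, width_px = 1) {
  m <- unclass(map)
  px_um <- attr(map, "pixel_size_um") %||% 1
  pl <- as.matrix(polyline)
  if (ncol(pl) != 2L || nrow(pl) < 2L)
    stop("polyline needs >= 2 (row, col) vertices")
  if (any(pl[, 1] < 1 | pl[, 1] > nrow(m) | pl[, 2] < 1 | pl[, 2] > ncol(m)))
    stop("polyline outside raster")
  bilinear <- function(r, c) {
    r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
    r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
    fr <- r - r0; fc <- c - c0
    m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      m[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  dist0 <- 0
  out <- list()
  for (s in seq_len(nrow(pl) - 1L)) {
    p0 <- pl[s, ]; p1 <- pl[s + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    nstep <- max(2L, ceiling(len) + 1L)
    tt <- seq(0, 1, length.out = nstep)
    if (s > 1L) tt <- tt[-1]
    rr <- p0[1] + tt * (p1[1] - p0[1])
    cc <- p0[2] + tt * (p1[2] - p0[2])
    dir <- (p1 - p0) / len
    perp <- c(-dir[2], dir[1])
    offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
    vals <- rowMeans(vapply(offs, function(o)
      bilinear(rr + o * perp[1], cc + o * perp[2]), numeric(length(tt))))
    out[[s]] <- data.frame(distance_mm = (dist0 + tt * len) * px_um / 1000,
                           value = vals)
    dist0 <- dist0 + len
  }
  do.call(rbind, out)
}

#' Correlation of segmented mineral density with an elemental ratio
#'
#' Ordinary least squares of the per-tissue mean ratio on the per-tissue
#' mean mineral density, with Pearson correlation and per-point residuals.
#'
#' @param points data.frame with columns `tissue`, `md` (mg/cc), `ratio`.
#' @return list `slope`, `intercept`, `r`, `residuals` (data.frame `tissue`,
#'   `md`, `ratio`, `fitted`, `residual`).
#' @export
md_vs_ratio_correlation <- function(points) {
  p <- as.data.frame(points)
  if (nrow(p) < 3L) stop("need >= 3 points")
  fit <- stats::lm(ratio ~ md, data = p)
  co <- stats::coef(fit)
  fitted <- as.numeric(stats::fitted(fit))
  r <- if (stats::sd(p$ratio) > 0) stats::cor(p$md, p$ratio) else 0
  list(slope = unname(co["md"]), intercept = unname(co["(Intercept)"]),
       r = r,
       residuals = data.frame(tissue = p$tissue, md = p$md, ratio = p$ratio,
                              fitted = fitted, residual = p$ratio - fitted))
}
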