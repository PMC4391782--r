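mk_map <- function(m, el = "Ca", units = "mmol_cm3")
  element_map(m, el, units = units)

test_that("map math computes pixelwise ratios with validity tracking", {
  ca <- mk_map(matrix(10, 4, 4))
  p <- mk_map(matrix(6, 4, 4), "P")
  r <- map_math(ca, p, "/")
  expect_equal(unique(as.numeric(unclass(r))), 10 / 6, tolerance = 1e-12)
  ## a map divided by itself is 1 on valid pixels
  r2 <- map_math(ca, ca, "/")
  expect_equal(unique(as.numeric(unclass(r2))), 1)
  ## zero-denominator pixels are invalid and excluded from stats
  pz <- mk_map(matrix(c(6, 0, 6, 6), 2, 2), "P")
  caz <- mk_map(matrix(10, 2, 2))
  rz <- map_math(caz, pz, "/")
  expect_equal(sum(attr(rz, "valid")), 3L)
  expect_equal(masked_stats(rz)$n_pixels, 3L)
  ## other ops preserve units, division is unit-safe only between like maps
  s <- map_math(ca, p, "-")
  expect_equal(unique(as.numeric(unclass(s))), 4)
  expect_error(map_math(ca, mk_map(matrix(1, 3, 3), "P"), "/"), "geometry")
})

test_that("masked statistics agree between methods on constant ratio fields", {
  ca <- mk_map(matrix(14.9, 8, 8))
  p <- mk_map(matrix(10, 8, 8), "P")
  r <- map_math(ca, p, "/")
  s1 <- masked_stats(r, method = "mean_of_ratios")
  s2 <- masked_stats(r, method = "ratio_of_means")
  expect_equal(s1$mean, 1.49)
  expect_equal(s2$mean, 1.49)
  expect_equal(s1$sd, 0)
  ## two-valued field {1, 3} with equal areas: mean-of-ratios is 2
  num <- mk_map(matrix(c(1, 3), 4, 4))
  den <- mk_map(matrix(1, 4, 4), "P")
  expect_equal(masked_stats(map_math(num, den, "/"))$mean, 2)
  expect_error(masked_stats(r, mask = matrix(FALSE, 8, 8)), "no valid")
})

test_that("generator ratio fields are recovered by masked means across seeds", {
  par <- data.frame(region = 1L, ca_mmolcc = 15.3, ca_p = 1.49)
  ctx <- absorption_context(2)
  std <- default_standards()
  means <- vapply(1:8, function(s) {
    xm <- make_xrf_maps(matrix(1L, 64, 64), par, ctx, std, noise_cv = 0.15,
                        seed = s)
    ca <- thickness_correct(calibrate_counts(xm$maps$Ca, std$Ca), ctx)
    p <- thickness_correct(calibrate_counts(xm$maps$P, std$P), ctx)
    masked_stats(map_math(ca, p, "/"))$mean
  }, numeric(1))
  ## unbiased recovery: grand mean within 2 sd of the seed means
  expect_lt(abs(mean(means) - 1.49), 2 * stats::sd(means))
})

test_that("density plots conserve counts and detect distinct zones", {
  set.seed(21)
  ## proportional maps: occupied bins on a line through the origin, one peak
  x <- matrix(runif(4096, 1, 2), 64, 64)
  a <- mk_map(x); b <- mk_map(1.5 * x, "P")
  dp <- density_plot(a, b, bins = 32L)
  expect_equal(sum(dp$counts), 4096L)
  occ <- which(dp$counts > 0, arr.ind = TRUE)
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  ratio <- mids(dp$b_edges)[occ[, 2]] / mids(dp$a_edges)[occ[, 1]]
  expect_lt(max(abs(ratio - 1.5)), 0.15)
  ## bimodal ratio mixture: two detected peaks (distinct lesion zones)
  ca <- matrix(10, 64, 64)
  pmat <- matrix(10 / 0.32, 64, 64)
  pmat[33:64, ] <- 10 / 0.46
  dp2 <- density_plot(mk_map(ca), mk_map(pmat, "P"), bins = 16L)
  expect_equal(nrow(dp2$peaks), 2L)
  expect_true(dp2$localized)
  ## masked counts conserved
  m <- matrix(FALSE, 64, 64); m[1:10, ] <- TRUE
  expect_equal(density_plot(a, b, mask = m)$n, sum(m))
})

test_that("bicolor overlays are pure views with channel dominance", {
  a <- mk_map(matrix(runif(64), 8, 8))
  zero <- mk_map(matrix(0, 8, 8), "Zn")
  ov <- bicolor_overlay(a, zero, colors = c("blue", "red"))
  ## b == 0: no red anywhere beyond blue's own contribution
  expect_equal(max(ov[, , 1]), 0)      # red channel empty
  expect_gt(max(ov[, , 3]), 0.9)       # blue channel carries a
  ## identical maps: equal channel mixture everywhere
  ov2 <- bicolor_overlay(a, mk_map(unclass(a), "Zn"))
  expect_equal(ov2[, , 1], ov2[, , 3])
  ## the input maps are untouched
  expect_equal(attr(a, "units"), "mmol_cm3")
  expect_true(all(is.finite(unclass(a))))
  expect_false(is.null(attr(ov, "normalization")))
})

test_that("line profiles reproduce flats, ramps and band periods", {
  flat <- mk_map(matrix(5, 16, 16))
  pf <- line_profile(flat, rbind(c(2, 2), c(14, 14)))
  expect_equal(unique(round(pf$value, 9)), 5)
  ramp <- mk_map(matrix(rep(1:16, 16), 16, 16))  # value = row index
  pr <- line_profile(ramp, rbind(c(1, 8), c(16, 8)))
  expect_equal(diff(pr$value), rep(1, 15), tolerance = 1e-9)
  ## distances scale with pixel size
  ramp2 <- element_map(matrix(rep(1:16, 16), 16, 16), "Ca", "mmol_cm3",
                       pixel_size_um = 500)
  pr2 <- line_profile(ramp2, rbind(c(1, 8), c(16, 8)))
  expect_equal(max(pr2$distance_mm), 15 * 0.5)
  expect_error(line_profile(flat, rbind(c(0, 1), c(5, 5))), "outside")
})

test_that("MD vs ratio correlation fits and flags collinearity", {
  pts <- data.frame(tissue = c("a", "b", "c", "d"),
                    md = c(900, 1100, 1300, 1500),
                    ratio = c(0.4, 0.8, 1.2, 1.6))
  fit <- md_vs_ratio_correlation(pts)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals$residual)), 0, tolerance = 1e-12)
  ## constant ratio: slope 0
  pts$ratio <- 1.5
  expect_equal(md_vs_ratio_correlation(pts)$slope, 0, tolerance = 1e-12)
  expect_error(md_vs_ratio_correlation(pts[1:2, ]), "3 points")
})

test_that("segmented tissue MD and Ca/P pairs show the expected positive trend", {
  ## normal-tissue panel: (mean MD, Ca/P) per tissue from the shipped configs
  md <- tissue_md_defaults()
  xr <- xrf_ratio_defaults()
  pts <- data.frame(
    tissue = c("dentin", "bone", "cementum", "lesion_zone1", "lesion_zone2"),
    md = c(md$md_mean[md$tissue == "dentin"],
           md$md_mean[md$tissue == "bone"],
           md$md_mean[md$tissue == "cementum"],
           md$md_mean[md$tissue == "hypomineralized_dentin"],
           md$md_mean[md$tissue == "hypomineralized_dentin"]),
    ratio = xr$ca_p[match(c("dentin", "bone", "cementum", "lesion_zone1",
                            "lesion_zone2"), xr$tissue)])
  fit <- md_vs_ratio_correlation(pts)
  expect_gt(fit$r, 0.5)
  expect_gt(fit$slope, 0)
})
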