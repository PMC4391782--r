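test_that("gradient magnitude is exact on flats and ramps and matches the oracle", {
  expect_equal(max(gradient_magnitude(array(5, c(4, 4, 4)))), 0)
  ## linear ramp slope s: interior magnitude s
  s <- 2.5
  a <- array(s * slice.index(array(0, c(4, 4, 6)), 3), c(4, 4, 6))
  g <- gradient_magnitude(a)
  expect_equal(unique(round(as.numeric(g[, , 2:5]), 9)), s)
  ## random volume vs brute-force oracle
  set.seed(11)
  b <- array(rnorm(64), c(4, 4, 4))
  expect_equal(unclass(gradient_magnitude(b)), oracle_gradmag(b),
               tolerance = 1e-12)
})

test_that("2D histogram conserves counts and resolves material plateaus", {
  ## constant volume: one occupied bin
  h0 <- histogram2d(array(3, c(4, 4, 4)), bins = c(16L, 16L))
  expect_equal(sum(h0$counts > 0), 1L)
  expect_equal(sum(h0$counts), 64L)
  ## two plateaus: two intensity columns at zero gradient + interface counts
  a <- array(100, c(6, 6, 8)); a[, , 5:8] <- 500
  g <- gradient_magnitude(a)
  h <- histogram2d(a, g, bins = c(32L, 8L))
  expect_equal(sum(h$counts), length(a))
  zero_grad_cols <- which(h$counts[, 1] > 0)
  expect_equal(length(zero_grad_cols), 2L)
  expect_true(any(h$counts[, -1] > 0))  # interface arch at elevated gradient
  ## masked conservation
  m <- array(FALSE, dim(a)); m[1:3, , ] <- TRUE
  hm <- histogram2d(a, g, bins = c(16L, 4L), mask = m)
  expect_equal(sum(hm$counts), sum(m))
  expect_error(histogram2d(a, g, mask = array(FALSE, dim(a))), "mask")
})

test_that("auto seed loci find one locus per material mode", {
  set.seed(5)
  one <- array(1000 + rnorm(8000, sd = 20), c(20, 20, 20))
  h1 <- histogram2d(one, bins = c(64L, 64L))
  l1 <- select_seed_loci(h1)
  expect_length(l1, 1L)
  two <- array(1000, c(20, 20, 20)); two[, , 11:20] <- 5000
  two <- two + rnorm(length(two), sd = 20)
  h2 <- histogram2d(two, bins = c(64L, 64L))
  l2 <- select_seed_loci(h2)
  expect_length(l2, 2L)
  ## loci bracket the plateau values, in increasing intensity order
  expect_true(l2[[1]]$intensity[1] < 1000 && 1000 < l2[[1]]$intensity[2])
  expect_true(l2[[2]]$intensity[1] < 5000 && 5000 < l2[[2]]$intensity[2])
  ## manual boxes: overlap rejected
  expect_error(select_seed_loci(h2, "manual", list(
    seed_locus(1, c(0, 10), c(0, 5)), seed_locus(2, c(5, 15), c(0, 5)))),
    "overlap")
  ## manual boxes identical to auto loci give identical downstream labels
  laba <- watershed_segment(two, l2)
  labm <- watershed_segment(two, select_seed_loci(h2, "manual", boxes = l2))
  expect_identical(unclass(laba), unclass(labm))
})

test_that("watershed places the boundary on the gradient crest", {
  ## 1-D two-basin landscape: values 1,1,5,1,1 with a marker in each basin
  g <- array(c(1, 1, 5, 1, 1), c(5, 1, 1))
  mk <- array(0L, c(5, 1, 1)); mk[1] <- 1L; mk[5] <- 2L
  lab <- oracle_watershed(g, mk)
  ## crest voxel (index 3) goes to the first-reached basin: label 1 by index
  expect_equal(as.integer(lab), c(1L, 1L, 1L, 2L, 2L))
  ## single locus: every masked voxel gets one label
  a <- array(rnorm(4^3, 100, 5), c(4, 4, 4))
  l <- watershed_segment(a, seed_locus(1, range(a) + c(-1, 1), c(-1, 1e6)))
  expect_true(all(unclass(l) == 1L))
  ## locus with no marker voxels errors by name
  expect_error(watershed_segment(a, seed_locus(7, c(1e5, 2e5), c(0, 1))),
               "locus 7")
})

test_that("watershed equals the brute-force flooding oracle on random volumes", {
  set.seed(99)
  for (rep in 1:25) {
    d <- sample(3:7, 3, replace = TRUE)
    g <- array(round(runif(prod(d)) * 10), d)  # ties exercised via rounding
    mk <- array(0L, d)
    k <- sample(2:3, 1)
    mk[sample(prod(d), k)] <- seq_len(k)
    ours <- mdxrf:::watershed_flood_core(g, mk)
    expect_identical(ours, oracle_watershed(g, mk))
  }
})

test_that("offsetting intensities shifts segment means but not labels", {
  acq <- acquisition_spec(noise_sd_hu = 50, blur_sigma_vox = 1)
  tv <- make_tissue_volume(list(tissue_region(1, 915, 20, z = c(1, 12)),
                                tissue_region(2, 1535, 27.5, z = c(13, 32))),
                           acq, ref_calib(), dim = c(32, 32, 32), seed = 2)
  hu <- scale_to_hu(tv$volume, acq$air_intensity, acq$water_intensity)
  g <- gradient_magnitude(hu)
  loci <- select_seed_loci(histogram2d(hu, g))
  lab <- watershed_segment(hu, loci, gradmag = g)
  st <- segment_stats(lab, hu)
  ## constant offset: same gradient, same labels, shifted means
  hu2 <- volume(unclass(hu) + 500, units = "HU")
  loci2 <- lapply(loci, function(l)
    seed_locus(l$locus_id, l$intensity + 500, l$gradient))
  lab2 <- watershed_segment(hu2, loci2, gradmag = g)
  expect_identical(as.integer(lab2), as.integer(lab))
  st2 <- segment_stats(lab2, hu2)
  expect_equal(st2$mean_hu, st$mean_hu + 500, tolerance = 1e-9)
})

test_that("noise-free two-region volumes are recovered exactly", {
  acq <- acquisition_spec(noise_sd_hu = 0, blur_sigma_vox = 0)
  cal <- ref_calib()
  tv <- make_tissue_volume(list(tissue_region(1, 915, 0, z = c(1, 12)),
                                tissue_region(2, 1535, 0, z = c(13, 32))),
                           acq, cal, dim = c(16, 16, 32))
  hu <- scale_to_hu(tv$volume, acq$air_intensity, acq$water_intensity)
  loci <- list(seed_locus(1, hu_from_md(915, cal) + c(-1, 1), c(-1, 1)),
               seed_locus(2, hu_from_md(1535, cal) + c(-1, 1), c(-1, 1)))
  lab <- watershed_segment(hu, loci)
  expect_equal(min(dice_coefficient(lab, tv$truth$labels)), 1)
  st <- segment_stats(lab, hu, cal)
  expect_equal(st$mean_md, c(915, 1535), tolerance = 1e-9)
  expect_equal(st$sd_md, c(0, 0), tolerance = 1e-9)
  ## partition: label counts sum to the volume
  expect_equal(sum(st$n_voxels), length(hu))
})

test_that("segment statistics convert HU to MD consistently", {
  cal <- ref_calib()
  lab <- array(rep(1:2, each = 32), c(4, 4, 4))
  v <- volume(array(c(rep(10000, 32), rep(14000, 32)), c(4, 4, 4)),
              voxel_size_um = 10, units = "HU")
  st <- segment_stats(lab, v, cal)
  expect_equal(st$mean_hu, c(10000, 14000))
  expect_equal(st$mean_md, 0.11 * c(10000, 14000) - 48.6)
  expect_equal(st$sd_hu, c(0, 0))
  expect_equal(st$volume_mm3, c(32, 32) * (10e-3)^3)
  expect_true(all(st$md_min <= st$mean_md & st$mean_md <= st$md_max))
})

test_that("slice profiles are flat for constant volumes and step at steps", {
  v <- volume(array(7, c(4, 4, 6)), units = "HU")
  p <- slice_profile(v)
  expect_equal(unique(p$mean_hu), 7)
  a <- array(100, c(4, 4, 6)); a[, , 4:6] <- 900
  p2 <- slice_profile(volume(a, units = "HU"), calib = ref_calib())
  expect_equal(p2$mean_hu, c(100, 100, 100, 900, 900, 900))
  expect_equal(p2$mean_md, 0.11 * p2$mean_hu - 48.6)
})

test_that("healthy-tissue profiles are flat up to the noise bound", {
  acq <- acquisition_spec(noise_sd_hu = 50, blur_sigma_vox = 0)
  tv <- make_tissue_volume(tissue_region(1, 1535, 0), acq, ref_calib(),
                           dim = c(32, 32, 32), seed = 4)
  hu <- scale_to_hu(tv$volume, acq$air_intensity, acq$water_intensity)
  p <- slice_profile(hu)
  ## per-slice mean sd bound: noise_sd / sqrt(n_per_slice), 3x margin
  expect_lt(stats::sd(p$mean_hu), 3 * 50 / sqrt(32 * 32))
})

test_that("dentin zone classification honors the HU cut-offs exactly", {
  st <- data.frame(mean_hu = c(10000, 14000, 15500, 3545, 13475, 13755,
                               14740, 13600, 15000, 2000))
  out <- classify_dentin_zones(st)
  expect_equal(out$zone,
               c("hypomineralized", "near_normal", "hypermineralized",
                 "hypomineralized", "hypomineralized", "near_normal",
                 "near_normal", "unclassified", "unclassified",
                 "unclassified"))
  expect_error(classify_dentin_zones(st, list(a = c(0, 10), b = c(5, 20))),
               "non-overlapping")
})
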