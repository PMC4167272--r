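strip_stack <- function(vals) image_stack(array(vals, c(length(vals), 1, 1)),
                                          spacing = 1)

test_that("the 6-SD threshold rule is exact arithmetic on the remote ROI", {
  # remote voxels mean 1.4, SD 0.1 -> cutoff 2.0; a 2.4 voxel is infarct
  vals <- c(1.3, 1.5, 1.3, 1.5, 2.4, 1.9)
  map <- strip_stack(vals)
  myo <- array(TRUE, dim(map$data))
  roi <- array(c(rep(TRUE, 4), FALSE, FALSE), dim(map$data))
  m <- threshold_classify(map, roi, myo, n_sd = 6)
  expect_equal(m$provenance$cutoff, 1.4 + 6 * sd(c(1.3, 1.5, 1.3, 1.5)))
  expect_equal(as.vector(m$mask$data), c(0, 0, 0, 0, 1, 0))
  # uniform map: nothing exceeds its own mean
  u <- strip_stack(rep(1.4, 6))
  expect_equal(sum(threshold_classify(u, roi, myo)$mask$data), 0)
  # degenerate SD = 0: cutoff collapses to the mean
  d <- strip_stack(c(1.4, 1.4, 1.4, 1.4, 1.5, 1.2))
  expect_equal(as.vector(threshold_classify(d, roi, myo)$mask$data),
               c(0, 0, 0, 0, 1, 0))
})

test_that("threshold classifier rejects unusable ROIs", {
  map <- strip_stack(1:6)
  myo <- array(TRUE, dim(map$data))
  none <- array(FALSE, dim(map$data))
  one <- none; one[1, 1, 1] <- TRUE
  expect_error(threshold_classify(map, none, myo), "empty")
  expect_error(threshold_classify(map, one, myo), "single voxel")
  outside <- array(TRUE, dim(map$data))
  myo2 <- none; myo2[1:3, 1, 1] <- TRUE
  expect_error(threshold_classify(map, outside, myo2), "within the myocardium")
})

test_that("the FWHM rule reproduces the hand-executed 1-D example", {
  map <- strip_stack(c(1, 1, 4, 8, 6, 1, 1))
  myo <- array(TRUE, dim(map$data))
  m <- fwhm_classify(map, c(3, 1, 1), myo)  # seed on the value-4 voxel
  # seed region {4, 8, 6} (>= 2), max 8, final >= 4 -> {4, 8, 6}
  expect_equal(as.vector(m$mask$data), c(0, 0, 1, 1, 1, 0, 0))
  # uniform map: everything is at 100% of the maximum
  u <- strip_stack(rep(3, 7))
  expect_equal(sum(fwhm_classify(u, c(5, 1, 1), myo)$mask$data), 7)
  expect_error(fwhm_classify(map, c(1, 1, 1), array(FALSE, dim(map$data))),
               "outside the myocardium")
})

test_that("FWHM restricts the final mask to components touching the seed region", {
  # a remote island above the cutoff must not be picked up
  vals <- c(10, 1, 1, 1, 9, 8, 1, 1, 6)
  map <- strip_stack(vals)
  myo <- array(TRUE, dim(map$data))
  m <- fwhm_classify(map, c(5, 1, 1), myo)
  # seed 9: growth >= 4.5 reaches {9, 8}; max 9 -> final >= 4.5, connected
  expect_equal(as.vector(m$mask$data), c(0, 0, 0, 0, 1, 1, 0, 0, 0))
})

test_that("classifier monotonicity in their tuning parameters", {
  st <- generate_phantom(small_phantom_config(snr = 25, seed = 3))
  maps <- lapply(st$dwi, function(d) fit_adc(st$b0, d, st$config$b_value))
  tr <- trace_adc(maps$x, maps$y, maps$z)
  myo <- st$truth$myocardium
  roi <- remote_roi_mask(myo, st$truth$reference_angle, st$truth$center)
  m6 <- threshold_classify(tr, roi, myo, n_sd = 6)
  m8 <- threshold_classify(tr, roi, myo, n_sd = 8)
  expect_true(all(m6$mask$data[m8$mask$data != 0] != 0))
  expect_lte(sum(m8$mask$data), sum(m6$mask$data))
  elev <- elevation_map(tr, roi)
  seeds <- dwcmr:::infarct_seeds(st$truth$infarct)
  f50 <- fwhm_classify(elev, seeds, myo, fraction = 0.5)
  f35 <- fwhm_classify(elev, seeds, myo, fraction = 0.35)
  expect_true(all(f35$mask$data[f50$mask$data != 0] != 0))
  expect_gte(sum(f35$mask$data), sum(f50$mask$data))
})

test_that("both classifiers recover the noise-free phantom infarct exactly", {
  st <- generate_phantom(small_phantom_config())
  maps <- lapply(st$dwi, function(d) fit_adc(st$b0, d, st$config$b_value))
  tr <- trace_adc(maps$x, maps$y, maps$z)
  myo <- st$truth$myocardium
  roi <- remote_roi_mask(myo, st$truth$reference_angle, st$truth$center)
  thr <- threshold_classify(tr, roi, myo)
  fw <- fwhm_classify(elevation_map(tr, roi),
                      dwcmr:::infarct_seeds(st$truth$infarct), myo)
  expect_equal(dice(thr, st$truth$infarct$data), 1)
  expect_equal(dice(fw, st$truth$infarct$data), 1)
})

test_that("FWHM recovers the lesion under noise at the default SNR", {
  st <- generate_phantom(small_phantom_config(snr = 30, seed = 8))
  maps <- lapply(st$dwi, function(d) fit_adc(st$b0, d, st$config$b_value))
  tr <- trace_adc(maps$x, maps$y, maps$z)
  myo <- st$truth$myocardium
  roi <- remote_roi_mask(myo, st$truth$reference_angle, st$truth$center)
  fw <- fwhm_classify(elevation_map(tr, roi),
                      dwcmr:::infarct_seeds(st$truth$infarct), myo)
  expect_gte(dice(fw, st$truth$infarct$data), 0.8)
})

test_that("infarct volume normalization and its guards", {
  st <- generate_phantom(small_phantom_config())
  myo <- st$truth$myocardium
  expect_equal(infarct_volume_pct(myo, myo), 100)
  empty <- array(0, dim(myo$data))
  expect_equal(infarct_volume_pct(empty, myo), 0)
  expect_error(infarct_volume_pct(empty, empty), "empty")
  everything <- array(1, dim(myo$data))
  expect_error(infarct_volume_pct(everything, myo), "outside")
  frac <- infarct_volume_pct(st$truth$infarct, myo)
  expect_equal(frac, 100 * sum(st$truth$infarct$data) / sum(myo$data))
})

test_that("transmurality separates full-wall from subendocardial wedges", {
  st <- generate_phantom(small_phantom_config())
  tm <- transmurality(st$truth$infarct, st$b0$contours,
                      center = st$truth$center)
  expect_true(all(tm$transmural))
  expect_equal(sort(unique(tm$slice)), c(2L, 3L))
  sub <- generate_phantom(small_phantom_config(transmural = FALSE))
  tm2 <- transmurality(sub$truth$infarct, sub$b0$contours,
                       center = sub$truth$center)
  expect_false(any(tm2$transmural))
  none <- transmurality(image_stack(array(0, dim(st$b0$data)),
                                    st$b0$spacing, st$b0$thickness),
                        st$b0$contours, center = st$truth$center)
  expect_equal(nrow(none), 0L)
})
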