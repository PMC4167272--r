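test_that("noise-free DWI follows the monoexponential forward model", {
  st <- generate_phantom(small_phantom_config())
  myo <- st$truth$myocardium$data != 0
  inf <- st$truth$infarct$data != 0
  remote <- myo & !inf
  # b * ADC = 400 s/mm^2 * 1.4e-3 mm^2/s = 0.56 in remote myocardium
  expect_equal(unique(st$dwi$x$data[remote]), 100 * exp(-0.56))
  expect_equal(unique(st$dwi$y$data[inf]), 100 * exp(-0.96))
  expect_equal(unique(st$b0$data[myo]), 100)
})

test_that("infarct fraction matches the configured geometry", {
  cfg <- phantom_config()
  expect_equal(true_infarct_fraction(cfg), 0.11, tolerance = 0.01)
  st <- generate_phantom(small_phantom_config())
  frac <- sum(st$truth$infarct$data) / sum(st$truth$myocardium$data)
  expect_lt(abs(frac - true_infarct_fraction(cfg)), 0.01)
  # halving the wedge roughly halves the fraction
  cfg2 <- phantom_config(infarct_extent_deg = 30)
  expect_equal(true_infarct_fraction(cfg2) / true_infarct_fraction(cfg), 0.5)
  # subendocardial option shrinks it further and keeps containment
  st3 <- generate_phantom(small_phantom_config(transmural = FALSE))
  expect_lt(sum(st3$truth$infarct$data), sum(st$truth$infarct$data))
})

test_that("phantom generation is deterministic for a fixed seed", {
  cfg <- small_phantom_config(snr = 20, snr_lge = 20, seed = 42)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$dwi$x$data, b$dwi$x$data)
  expect_identical(a$lge$data, b$lge$data)
  c <- generate_phantom(small_phantom_config(snr = 20, snr_lge = 20, seed = 43))
  expect_false(identical(a$dwi$x$data, c$dwi$x$data))
})

test_that("ground-truth masks are mutually consistent", {
  st <- generate_phantom(small_phantom_config())
  myo <- st$truth$myocardium$data != 0
  inf <- st$truth$infarct$data != 0
  expect_true(all(myo[inf]))          # infarct within myocardium
  # myocardium is an annulus: every masked voxel lies between the radii
  cfg <- st$config
  g <- dwcmr:::grid_coords(st$b0)
  for (s in 1:3) {
    idx <- which(myo[, , s], arr.ind = TRUE)
    r <- sqrt((g$x[idx[, 1]] - cfg$fov / 2)^2 + (g$y[idx[, 2]] - cfg$fov / 2)^2)
    expect_true(all(r > cfg$endo_radii[s] & r <= cfg$epi_radii[s]))
  }
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(infarct_extent_deg = 400), "extent")
  expect_error(phantom_config(endo_radii = c(30, 17, 12)), "endo radius")
  expect_error(phantom_config(epi_radii = c(-1, 27, 22)), "positive")
  expect_error(phantom_config(remote_excursion = -2), "non-negative")
  expect_error(phantom_config(snr = 0), "SNR")
  expect_error(phantom_config(adc_infarct = 1.0), "infarct ADC")
  expect_error(phantom_config(infarct_slices = c(2, 7)), "slice span")
})

test_that("cine motion reproduces the configured radial excursions", {
  cfg <- small_phantom_config()
  cine <- simulate_cine(cfg)
  rwm <- chord_displacement(cine)
  remote <- sector_rwm(rwm, 255, 60, cfg$reference_angle, slices = 1L)
  infz <- sector_rwm(rwm, cfg$infarct_center_deg - cfg$infarct_extent_deg / 2,
                     cfg$infarct_extent_deg, cfg$reference_angle, slices = 2:3)
  expect_equal(remote$mean, 8.3, tolerance = 0.05)
  expect_equal(infz$mean, 0.9, tolerance = 0.05)
  # zero excursion everywhere: all phases share identical contours
  cfg0 <- small_phantom_config(remote_excursion = 0, infarct_excursion = 0,
                               tether_excursion = 0)
  cine0 <- simulate_cine(cfg0)
  expect_equal(cine0$contours[[1]], cine0$contours[[7]])
  # phase 0 is end-diastole: maximal cavity radius
  r0 <- dwcmr:::ray_polygon_radius(cine$contours[[1]][[1]]$endo,
                                   c(cfg$fov / 2, cfg$fov / 2), 10)
  rmid <- dwcmr:::ray_polygon_radius(cine$contours[[7]][[1]]$endo,
                                     c(cfg$fov / 2, cfg$fov / 2), 10)
  expect_gt(r0, rmid)
})

test_that("Rician noise has the expected limits and is seeded", {
  st <- generate_phantom(small_phantom_config())
  hi <- add_rician_noise(st$b0, snr = 1e9, seed = 1)
  expect_lt(max(abs(hi$data - st$b0$data)) / max(st$b0$data), 1e-6)
  # Rayleigh background: zero-signal mean -> sigma * sqrt(pi / 2)
  zero <- image_stack(array(0, c(120, 120, 1)), spacing = 1)
  sigma <- 5
  noisy <- add_rician_noise(zero, snr = 100 / sigma, seed = 7, reference = 100)
  expect_equal(mean(noisy$data), sigma * sqrt(pi / 2), tolerance = 0.02)
  expect_identical(add_rician_noise(zero, 10, seed = 3)$data,
                   add_rician_noise(zero, 10, seed = 3)$data)
  expect_error(add_rician_noise(zero, -1, seed = 1), "positive")
})

test_that("raising infarct ADC strictly deepens noise-free DWI attenuation", {
  base <- generate_phantom(small_phantom_config())
  high <- generate_phantom(small_phantom_config(adc_infarct = 3.0))
  inf <- base$truth$infarct$data != 0
  expect_true(all(high$dwi$x$data[inf] < base$dwi$x$data[inf]))
})

test_that("phantom NIfTI round trip preserves data and geometry", {
  st <- generate_phantom(small_phantom_config())
  dir <- withr::local_tempdir()
  write_phantom(st, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_image_stack(file.path(dir, "b0.nii.gz"))
  expect_equal(back$data, st$b0$data, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(back$spacing, st$b0$spacing, tolerance = 1e-6)
  expect_equal(back$thickness, st$b0$thickness)
})
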