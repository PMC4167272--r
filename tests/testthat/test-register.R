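test_that("phase matching finds the acquisition phase and breaks ties early", {
  cfg <- small_phantom_config()
  st <- generate_phantom(cfg)
  expect_equal(select_matching_phase(st$cine, st$b0), cfg$b0_phase)
  expect_equal(select_matching_phase(st$cine, st$lge), cfg$lge_phase)
  # target equal to an arbitrary phase's contours
  expect_equal(select_matching_phase(st$cine, st$cine$contours[[5]]), 4L)
  # motionless cine: all phases tie, earliest wins
  cfg0 <- small_phantom_config(remote_excursion = 0, infarct_excursion = 0,
                               tether_excursion = 0)
  st0 <- generate_phantom(cfg0)
  expect_equal(select_matching_phase(st0$cine, st0$cine$contours[[4]]), 0L)
  empty <- list(contours = list(), n_phases = 0)
  expect_error(select_matching_phase(empty, st$b0), "no phases")
})

test_that("identity and pure-translation fits are exact", {
  set.seed(4)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  src <- cbind(50 + 20 * cos(th), 50 + 18 * sin(th))
  xfm_id <- fit_bspline(src, src, grid_spacing = 20, lambda = 0)
  expect_lt(max(abs(eval_bspline(xfm_id, src))), 1e-8)
  expect_lt(xfm_id$residuals, 1e-8)
  dst <- cbind(src[, 1] + 3, src[, 2] - 2)
  xfm_t <- fit_bspline(src, dst, grid_spacing = 20, lambda = 0)
  u <- eval_bspline(xfm_t, src)
  expect_lt(max(abs(u[, 1] - 3)), 1e-6)
  expect_lt(max(abs(u[, 2] + 2)), 1e-6)
})

test_that("degenerate landmark sets are rejected with a reason", {
  p3 <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(fit_bspline(p3, p3), "at least 4")
  line <- cbind(1:10, 2 * (1:10) + 1)
  expect_error(fit_bspline(line, line), "collinear")
  a <- cbind(runif(8, 0, 10), runif(8, 0, 10))
  expect_error(fit_bspline(a, a[1:5, ]), "length")
})

test_that("the phantom's known warp is recovered below half a pixel", {
  # lge_phase 3 of 12 gives the same contraction factor (~0.5) as the full
  # 35-phase protocol's acquisition phase, i.e. the same warp magnitude
  cfg <- small_phantom_config(lge_phase = 3)
  st <- generate_phantom(cfg)
  src <- list(); dst <- list()
  for (s in 1:3) {
    cb <- st$cine$contours[[cfg$b0_phase + 1]][[s]]
    pts <- rbind(contour_landmarks(cb$endo, 50), contour_landmarks(cb$epi, 50))
    src[[s]] <- pts
    dst[[s]] <- pts + st$truth$displacement(pts, s)
  }
  # the reduced-phase fixture is sampled nearer peak systole, so the warp is
  # larger than the full protocol's; a finer lattice keeps the fit sharp
  xfm <- fit_bspline(src, dst, grid_spacing = 15, lambda = 1e-3,
                     domain = c(0, cfg$fov, 0, cfg$fov))
  px <- cfg$spacing_lge
  for (s in 1:3) {
    u <- eval_bspline(xfm, src[[s]], s)
    rmse <- sqrt(mean(rowSums((u - (dst[[s]] - src[[s]]))^2)))
    expect_lt(rmse / px, 0.5)
  }
})

test_that("apply_transform: identity, whole-pixel shifts, and warp inversion", {
  st <- generate_phantom(small_phantom_config())
  img <- st$lge
  n_ctrl <- 10
  id <- fit_bspline(replicate(3, cbind(runif(n_ctrl, 10, 110),
                                       runif(n_ctrl, 10, 110)),
                              simplify = FALSE),
                    replicate(3, cbind(runif(n_ctrl, 10, 110),
                                       runif(n_ctrl, 10, 110)),
                              simplify = FALSE),
                    domain = c(0, 120.4, 0, 120.4))
  for (s in 1:3) {
    id$slices[[s]]$cx[] <- 0
    id$slices[[s]]$cy[] <- 0
  }
  expect_equal(apply_transform(img, id)$data, img$data)
  # uniform shift of exactly 2 pixels, nearest interpolation
  shift <- id
  for (s in 1:3) shift$slices[[s]]$cx[] <- 2 * img$spacing[1]
  shifted <- apply_transform(img, shift, interpolation = "nearest")
  nx <- dim(img$data)[1]
  expect_equal(shifted$data[1:(nx - 2), , 2], img$data[3:nx, , 2])
  # warp then inverse-warp restores a smooth image to interpolation accuracy
  g <- dwcmr:::grid_coords(img)
  smooth <- img
  for (s in 1:3) {
    smooth$data[, , s] <- outer(g$x, g$y, function(x, y) {
      exp(-((x - 60)^2 + (y - 55)^2) / 800)
    })
  }
  warp <- id; inv <- id
  for (s in 1:3) {
    warp$slices[[s]]$cx[] <- 3; warp$slices[[s]]$cy[] <- -2
    inv$slices[[s]]$cx[] <- -3; inv$slices[[s]]$cy[] <- 2
  }
  round_trip <- apply_transform(apply_transform(smooth, warp), inv)
  interior <- 10:80
  expect_lt(max(abs(round_trip$data[interior, interior, 1] -
                    smooth$data[interior, interior, 1])), 5e-3)
})

test_that("stronger regularization monotonically lowers bending energy", {
  set.seed(9)
  th <- seq(0, 2 * pi, length.out = 31)[-31]
  src <- cbind(60 + 25 * cos(th), 60 + 25 * sin(th))
  dst <- src + matrix(rnorm(length(src), 0, 1.5), ncol = 2)
  be <- vapply(c(1e-4, 1e-2, 1, 100), function(l) {
    bending_energy(fit_bspline(src, dst, grid_spacing = 15, lambda = l))
  }, numeric(1))
  expect_true(all(diff(be) < 0))
})
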