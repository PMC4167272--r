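circle <- function(r, ctr = c(0, 0), n = 90) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

make_chord_map <- function(disp_by_slice, n = 100) {
  angles <- seq(0, 360, length.out = n + 1)[seq_len(n)]
  structure(list(
    slices = lapply(disp_by_slice, function(d) {
      list(angles = angles, displacement = rep_len(d, n))
    }),
    n = n, reference_phase = 0L,
    centers = rep(list(c(0, 0)), length(disp_by_slice))),
    class = "chord_displacement_map")
}

test_that("chords on concentric circles are uniform and evenly spaced", {
  ch <- compute_chords(circle(15), circle(25), n = 100)
  expect_length(ch$angles, 100)
  expect_equal(ch$length, rep(10, 100), tolerance = 1e-3)
  ch4 <- compute_chords(circle(15), circle(25), n = 4)
  expect_equal(diff(ch4$angles), rep(90, 3))
  expect_error(compute_chords(circle(26), circle(25)), "cross")
})

test_that("phantom chords intersect each contour exactly once", {
  st <- generate_phantom(small_phantom_config())
  for (s in 1:3) {
    c0 <- st$cine$contours[[1]][[s]]
    ch <- compute_chords(c0$endo, c0$epi, n = 100)
    expect_length(ch$endo_r, 100)
    expect_true(all(ch$epi_r > ch$endo_r))
  }
})

test_that("a motionless cine yields zero displacement everywhere", {
  cfg <- small_phantom_config(remote_excursion = 0, infarct_excursion = 0,
                              tether_excursion = 0)
  rwm <- chord_displacement(simulate_cine(cfg))
  expect_equal(max(unlist(lapply(rwm$slices, `[[`, "displacement"))), 0)
})

test_that("phantom displacement hits the configured remote and infarct levels", {
  cfg <- small_phantom_config()
  rwm <- chord_displacement(simulate_cine(cfg))
  remote <- sector_rwm(rwm, 255, 60, cfg$reference_angle, slices = 1L)
  infz <- sector_rwm(rwm, 80, 50, cfg$reference_angle, slices = 2:3)
  expect_equal(remote$mean, 8.3, tolerance = 0.1)
  expect_equal(infz$mean, 0.9, tolerance = 0.1)
})

test_that("displacement is invariant under joint rigid translation", {
  cfg <- small_phantom_config()
  cine <- simulate_cine(cfg)
  moved <- cine
  for (p in seq_along(cine$contours)) {
    for (s in seq_along(cine$contours[[p]])) {
      for (cn in c("endo", "epi")) {
        moved$contours[[p]][[s]][[cn]] <-
          cine$contours[[p]][[s]][[cn]] + rep(c(7, -4), each = nrow(cine$contours[[p]][[s]][[cn]]))
      }
    }
  }
  d0 <- chord_displacement(cine)$slices[[1]]$displacement
  d1 <- chord_displacement(moved)$slices[[1]]$displacement
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("the 3 mm rule classifies akinetic segments from mean chord motion", {
  labels3 <- lapply(c("basal", "mid", "apical"), function(lv) {
    aha_chord_segments(seq(0, 360, length.out = 101)[1:100], lv, 0)
  })
  none <- classify_akinetic(make_chord_map(list(8.3, 8.3, 8.3)), labels3)
  expect_equal(sum(none), 0)
  all16 <- classify_akinetic(make_chord_map(list(0, 0, 0)), labels3)
  expect_equal(sum(all16), 16)
  # one mid segment at 1 mm, everything else remote
  disp_mid <- ifelse(labels3[[2]] == 8L, 1, 8.3)
  one <- classify_akinetic(make_chord_map(list(8.3, disp_mid, 8.3)), labels3)
  expect_equal(which(one == 1L), 8L)
  bad <- labels3
  bad[[1]][5] <- NA
  expect_error(classify_akinetic(make_chord_map(list(1, 1, 1)), bad), "label")
})

test_that("missing contours are reported with their phase", {
  cfg <- small_phantom_config()
  cine <- simulate_cine(cfg)
  cine$contours[[4]] <- NULL
  expect_error(chord_displacement(cine), "phase")
})
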