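#' Configuration of the digital left-ventricle phantom
#'
#' Builds the parameter set for a ground-truthed three-slice short-axis LV
#' phantom emulating a chronic-infarct dwCMR study: a b0 image, three
#' orthogonal diffusion-weighted images, an LGE-like hyperenhancement image
#' acquired in a different (deformed) cardiac phase, and a multi-phase cine
#' series with endo/epicardial contours. The defaults reproduce the study
#' conditions the analysis targets: 3 slices of 6 mm, in-plane resolutions of
#' 2.1 mm (DWI), 1.3 mm (LGE) and 1.4 mm (cine), 35 cardiac phases, a
#' transmural anteroseptal (LAD-territory) wedge infarct occupying ~11% of the
#' imaged LV myocardium, remote trace ADC 1.4 vs infarct 2.4 um^2/ms, remote
#' radial wall excursion 8.3 mm vs 0.9 mm in the infarct, and Rician noise.
#'
#' Angles: the anatomical angle `alpha` is measured counter-clockwise from the
#' anterior reference ray (`reference_angle`, stored in image coordinates).
#' The infarct wedge is centred at `infarct_center_deg` (alpha coordinates)
#' with full width `infarct_extent_deg`, and spans `infarct_slices` (slice 1 =
#' base). Wall-motion deficit extends `akinetic_margin_deg` beyond the wedge
#' with a `motion_ramp_deg` linear ramp back to the remote excursion, and a
#' reduced "tethering" excursion on slices adjacent to the infarct.
#'
#' @param fov in-plane field of view (mm).
#' @param spacing_dwi,spacing_lge,spacing_cine in-plane pixel spacings (mm).
#' @param thickness slice thickness (mm).
#' @param endo_radii,epi_radii end-diastolic endo/epicardial radii per slice
#'   (mm, base, mid, apex).
#' @param infarct_extent_deg angular full width of the infarct wedge (deg).
#' @param infarct_center_deg wedge centre in alpha coordinates (deg).
#' @param infarct_slices slice indices carrying infarct.
#' @param transmural logical; `FALSE` confines the infarct to the inner
#'   (subendocardial) half of the wall.
#' @param adc_remote,adc_infarct,adc_blood true trace ADC levels (um^2/ms).
#' @param b_value diffusion weighting (s/mm^2).
#' @param s0_myo,s0_blood b0 signal amplitudes.
#' @param lge_remote,lge_infarct,lge_blood LGE intensity levels (blood is
#'   isointense with remote myocardium, as in a nulled PSIR acquisition).
#' @param cine_myo,cine_blood,cine_background cine intensity levels.
#' @param n_phases number of cardiac phases.
#' @param remote_excursion,infarct_excursion,tether_excursion peak radial
#'   endocardial excursions (mm) in remote myocardium, the infarct zone, and
#'   the tethered zone of adjacent slices.
#' @param akinetic_margin_deg,motion_ramp_deg angular extent (deg) of the
#'   motion-deficit plateau beyond the wedge, and of the linear ramp back to
#'   remote motion.
#' @param epi_excursion_frac epicardial excursion as a fraction of
#'   endocardial excursion.
#' @param reference_angle image-coordinate angle (deg, CCW from +x) of the
#'   anterior reference ray.
#' @param b0_phase,lge_phase cardiac phases (0-based) at which the b0/DWI and
#'   LGE images are acquired.
#' @param snr,snr_lge,snr_cine Rician signal-to-noise ratios (relative to the
#'   remote-myocardium b0 amplitude, the infarct LGE amplitude, and the cine
#'   blood amplitude); `Inf` disables noise.
#' @param store_cine_images logical; render cine intensity images (contours
#'   are always generated).
#' @param seed RNG seed controlling all phantom noise.
#' @return A `phantom_config` list, validated against the model invariants.
#' @export
phantom_config <- function(fov = 201.6,
                           spacing_dwi = 2.1,
                           spacing_lge = 1.3,
                           spacing_cine = 1.4,
                           thickness = 6,
                           endo_radii = c(21, 17, 12),
                           epi_radii = c(29, 27, 22),
                           infarct_extent_deg = 60,
                           infarct_center_deg = 105,
                           infarct_slices = c(2L, 3L),
                           transmural = TRUE,
                           adc_remote = 1.4,
                           adc_infarct = 2.4,
                           adc_blood = 3.0,
                           b_value = 400,
                           s0_myo = 100,
                           s0_blood = 150,
                           lge_remote = 20,
                           lge_infarct = 100,
                           lge_blood = 20,
                           cine_myo = 80,
                           cine_blood = 160,
                           cine_background = 10,
                           n_phases = 35,
                           remote_excursion = 8.3,
                           infarct_excursion = 0.9,
                           tether_excursion = 2.5,
                           akinetic_margin_deg = 50,
                           motion_ramp_deg = 10,
                           epi_excursion_frac = 0.35,
                           reference_angle = 120,
                           b0_phase = 0L,
                           lge_phase = 8L,
                           snr = 30,
                           snr_lge = 40,
                           snr_cine = 40,
                           store_cine_images = TRUE,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (length(endo_radii) != length(epi_radii)) {
      stop_dwcmr("endo and epi radii must be given for the same slices")
    }
    if (any(endo_radii <= 0) || any(epi_radii <= 0)) {
      stop_dwcmr("radii must be positive")
    }
    if (any(endo_radii >= epi_radii)) {
      stop_dwcmr("endo radius must be smaller than epi radius on every slice")
    }
    if (infarct_extent_deg <= 0 || infarct_extent_deg > 360) {
      stop_dwcmr("infarct angular extent must be in (0, 360] degrees ",
                 "(wider would exceed the myocardium)")
    }
    if (any(infarct_slices < 1) || any(infarct_slices > length(endo_radii))) {
      stop_dwcmr("infarct slice span exceeds the acquired slices")
    }
    if (adc_infarct <= adc_remote) {
      stop_dwcmr("infarct ADC must exceed remote ADC")
    }
    if (remote_excursion < 0 || infarct_excursion < 0 || tether_excursion < 0) {
      stop_dwcmr("excursions must be non-negative")
    }
    if (snr <= 0 || snr_lge <= 0 || snr_cine <= 0) stop_dwcmr("SNR must be positive")
    if (n_phases < 2) stop_dwcmr("at least two cardiac phases are required")
    if (2 * max(epi_radii) >= fov) stop_dwcmr("LV does not fit in the field of view")
  })
  invisible(cfg)
}

# ---- internal geometry -----------------------------------------------------

# Systolic contraction factor per 0-based phase: 0 at end-diastole (phase 0),
# 1 at mid-systole.
phase_factor <- function(phase, n_phases) {
  (1 - cos(2 * pi * phase / n_phases)) / 2
}

# Peak endocardial excursion (mm) at anatomical angle alpha (deg) on `slice`.
# Plateau at the deficit level over the wedge +/- margin, linear ramp of
# `motion_ramp_deg` back to the remote level.
excursion_profile <- function(cfg, alpha, slice) {
  deficit <- if (slice %in% cfg$infarct_slices) {
    cfg$infarct_excursion
  } else if (any(abs(slice - cfg$infarct_slices) == 1L)) {
    cfg$tether_excursion
  } else {
    cfg$remote_excursion
  }
  if (deficit >= cfg$remote_excursion) {
    return(rep(cfg$remote_excursion, length(alpha)))
  }
  half <- cfg$infarct_extent_deg / 2 + cfg$akinetic_margin_deg
  d <- wrap360(alpha - cfg$infarct_center_deg)
  d <- pmin(d, 360 - d)                       # distance to wedge centre
  t <- pmin(pmax((d - half) / cfg$motion_ramp_deg, 0), 1)
  deficit + (cfg$remote_excursion - deficit) * t
}

# Endo/epi radii (mm) at a given phase, as functions of alpha, per slice.
slice_radii <- function(cfg, slice, alpha, phase) {
  s <- phase_factor(phase, cfg$n_phases)
  exc <- excursion_profile(cfg, alpha, slice)
  list(
    endo = cfg$endo_radii[slice] - exc * s,
    epi  = cfg$epi_radii[slice] - cfg$epi_excursion_frac * exc * s
  )
}

# Closed endo/epi contours (world mm) for every slice at `phase`.
phantom_contours <- function(cfg, phase, npts = 180L) {
  ctr <- cfg$fov / 2
  theta <- seq(0, 360, length.out = npts + 1L)[-(npts + 1L)]
  alpha <- wrap360(theta - cfg$reference_angle)
  rad <- theta * pi / 180
  lapply(seq_along(cfg$endo_radii), function(s) {
    r <- slice_radii(cfg, s, alpha, phase)
    list(
      endo = cbind(ctr + r$endo * cos(rad), ctr + r$endo * sin(rad)),
      epi  = cbind(ctr + r$epi * cos(rad), ctr + r$epi * sin(rad))
    )
  })
}

# Polar coordinate maps (r in mm, alpha in deg) for a square grid.
polar_maps <- function(cfg, spacing) {
  n <- round(cfg$fov / spacing)
  x <- (seq_len(n) - 0.5) * spacing
  ctr <- cfg$fov / 2
  X <- matrix(x, n, n)
  Y <- matrix(x, n, n, byrow = TRUE)
  r <- sqrt((X - ctr)^2 + (Y - ctr)^2)
  alpha <- wrap360(angle_deg(X, Y, ctr, ctr) - cfg$reference_angle)
  list(n = n, r = r, alpha = alpha)
}

# Per-slice logical masks (myocardium, infarct) on a grid at `phase`.
phantom_masks <- function(cfg, spacing, phase) {
  pm <- polar_maps(cfg, spacing)
  nsl <- length(cfg$endo_radii)
  myo <- array(FALSE, c(pm$n, pm$n, nsl))
  inf <- array(FALSE, c(pm$n, pm$n, nsl))
  blood <- array(FALSE, c(pm$n, pm$n, nsl))
  wedge_from <- cfg$infarct_center_deg - cfg$infarct_extent_deg / 2
  for (s in seq_len(nsl)) {
    rr <- slice_radii(cfg, s, as.vector(pm$alpha), phase)
    endo <- matrix(rr$endo, pm$n, pm$n)
    epi <- matrix(rr$epi, pm$n, pm$n)
    myo[, , s] <- pm$r > endo & pm$r <= epi
    blood[, , s] <- pm$r <= endo
    if (s %in% cfg$infarct_slices) {
      m <- myo[, , s] & in_sector(pm$alpha, wedge_from, cfg$infarct_extent_deg)
      if (!cfg$transmural) m <- m & pm$r <= (endo + epi) / 2
      inf[, , s] <- m
    }
  }
  list(myo = myo, infarct = inf, blood = blood, polar = pm)
}

# True radial displacement (mm, signed along the outward ray; negative =
# inward) of the material point at rest position (r, alpha) on `slice`, going
# from phase 0 to `phase`. Linear through-wall interpolation between the
# endocardial and epicardial excursions, decaying to zero 15 mm outside the
# epicardium and towards the LV centre.
radial_displacement <- function(cfg, r, alpha, slice, phase) {
  s <- phase_factor(phase, cfg$n_phases)
  exc <- excursion_profile(cfg, alpha, slice)
  re <- cfg$endo_radii[slice]
  rp <- cfg$epi_radii[slice]
  f <- cfg$epi_excursion_frac
  w <- numeric(length(r))
  inside <- r <= re
  wall <- r > re & r <= rp
  outer <- r > rp
  w[inside] <- r[inside] / re
  w[wall] <- 1 + (f - 1) * (r[wall] - re) / (rp - re)
  w[outer] <- f * pmax(0, 1 - (r[outer] - rp) / 15)
  -s * exc * w
}

#' Analytic infarct fraction of the phantom
#'
#' Continuous (pre-discretization) infarct volume fraction of the three-slice
#' LV myocardium implied by a phantom configuration.
#'
#' @param cfg a [phantom_config()].
#' @return Fraction in `[0, 1]`.
#' @export
true_infarct_fraction <- function(cfg) {
  area <- cfg$epi_radii^2 - cfg$endo_radii^2   # per-slice annulus area / pi
  inf_area <- vapply(seq_along(area), function(s) {
    if (!(s %in% cfg$infarct_slices)) return(0)
    if (cfg$transmural) area[s]
    else ((cfg$endo_radii[s] + cfg$epi_radii[s]) / 2)^2 - cfg$endo_radii[s]^2
  }, numeric(1))
  (cfg$infarct_extent_deg / 360) * sum(inf_area) / sum(area)
}

# ---- noise -----------------------------------------------------------------

#' Add Rician (magnitude-MR) noise to an image stack
#'
#' Models the magnitude of complex Gaussian noise added to a real-valued
#' signal: `out = sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)` and
#' `sigma = reference / snr`. In zero-signal regions the output mean tends to
#' `sigma * sqrt(pi/2)`, the Rayleigh background of magnitude MR images.
#'
#' @param image an [image_stack()].
#' @param snr signal-to-noise ratio (> 0); `Inf` returns the input unchanged.
#' @param seed RNG seed.
#' @param reference amplitude defining `sigma`; defaults to the 99th
#'   percentile of the image.
#' @return A noisy `image_stack` with the same geometry.
#' @export
add_rician_noise <- function(image, snr, seed, reference = NULL) {
  if (!is.numeric(snr) || is.na(snr) || snr <= 0) stop_dwcmr("`snr` must be positive")
  if (is.infinite(snr)) return(image)
  reference <- reference %||% as.numeric(stats::quantile(abs(image$data), 0.99))
  sigma <- reference / snr
  noisy <- with_seed(seed, {
    n <- length(image$data)
    sqrt((image$data + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  })
  out <- image
  out$data <- array(noisy, dim = dim(image$data))
  out
}

# ---- cine ------------------------------------------------------------------

#' Simulate the cine series of the phantom
#'
#' Generates per-phase LV endo/epicardial contours (and optionally bSSFP-like
#' intensity images) over the cardiac cycle. Phase 0 is end-diastole (maximal
#' cavity); the radial endocardial excursion over the cycle equals the
#' configured remote excursion outside the infarct motion-deficit zone and the
#' configured infarct excursion inside it.
#'
#' @param cfg a [phantom_config()].
#' @return A `cine_study`: list with `contours[[phase]][[slice]]` (`endo`,
#'   `epi` matrices in world mm), optional `images` (list of `image_stack`
#'   per phase), `n_phases`, `center` (LV centre, mm), and `spacing`.
#' @export
simulate_cine <- function(cfg) {
  validate_phantom_config(cfg)
  phases <- seq_len(cfg$n_phases) - 1L
  contours <- lapply(phases, function(p) phantom_contours(cfg, p))
  images <- NULL
  if (isTRUE(cfg$store_cine_images)) {
    images <- lapply(phases, function(p) {
      m <- phantom_masks(cfg, cfg$spacing_cine, p)
      img <- array(cfg$cine_background, dim = dim(m$myo))
      img[m$blood] <- cfg$cine_blood
      img[m$myo] <- cfg$cine_myo
      stk <- image_stack(img, cfg$spacing_cine, cfg$thickness,
                         contours = contours[[p + 1L]])
      add_rician_noise(stk, cfg$snr_cine, seed = phantom_seed(cfg$seed, 100L + p),
                       reference = cfg$cine_blood)
    })
  }
  structure(
    list(contours = contours, images = images, n_phases = cfg$n_phases,
         center = c(cfg$fov / 2, cfg$fov / 2), spacing = cfg$spacing_cine),
    class = "cine_study"
  )
}

#' @export
print.cine_study <- function(x, ...) {
  cat(sprintf("<cine_study> %d phases, %d slices%s\n", x$n_phases,
              length(x$contours[[1]]),
              if (is.null(x$images)) " (contours only)" else " with images"))
  invisible(x)
}

# Derived sub-seed, kept below 2^31.
phantom_seed <- function(seed, k) (as.double(seed) * 131 + k) %% 2147483647

# ---- phantom ---------------------------------------------------------------

#' Generate the full phantom study
#'
#' Renders all acquisitions of the emulated study from one configuration:
#' b0, three orthogonal diffusion-weighted stacks (noise-free myocardial DWI
#' signal `S0 * exp(-b * ADC)` with ADC in mm^2/s), an LGE-like image rendered
#' in the deformed geometry of a different cardiac phase, the cine series, and
#' the ground truth (true ADC map, myocardium and infarct masks on the DWI and
#' LGE grids, the true inter-phase displacement field, and the true per-angle
#' wall excursion). Deterministic for a fixed seed.
#'
#' @param cfg a [phantom_config()].
#' @return A `phantom_study` list: `b0`, `dwi` (list `x`, `y`, `z`), `lge`,
#'   `cine`, `truth`, `config`.
#' @export
generate_phantom <- function(cfg) {
  validate_phantom_config(cfg)
  ctr <- c(cfg$fov / 2, cfg$fov / 2)

  # --- DWI-grid geometry at the b0 phase (end-diastole) ---
  mk <- phantom_masks(cfg, cfg$spacing_dwi, cfg$b0_phase)
  adc_true <- array(NA_real_, dim = dim(mk$myo))
  adc_true[mk$blood] <- cfg$adc_blood
  adc_true[mk$myo] <- cfg$adc_remote
  adc_true[mk$infarct] <- cfg$adc_infarct

  s0 <- array(0, dim = dim(mk$myo))
  s0[mk$blood] <- cfg$s0_blood
  s0[mk$myo] <- cfg$s0_myo

  atten <- array(1, dim = dim(mk$myo))
  def <- !is.na(adc_true)
  atten[def] <- exp(-cfg$b_value * adc_true[def] * 1e-3)
  sb <- s0 * atten

  b0_contours <- phantom_contours(cfg, cfg$b0_phase)
  b0 <- image_stack(s0, cfg$spacing_dwi, cfg$thickness, contours = b0_contours)
  dwi_clean <- image_stack(sb, cfg$spacing_dwi, cfg$thickness)

  b0_noisy <- add_rician_noise(b0, cfg$snr, phantom_seed(cfg$seed, 1L),
                               reference = cfg$s0_myo)
  dwi <- lapply(seq_len(3L), function(k) {
    add_rician_noise(dwi_clean, cfg$snr, phantom_seed(cfg$seed, 1L + k),
                     reference = cfg$s0_myo)
  })
  names(dwi) <- c("x", "y", "z")

  # --- LGE in the deformed geometry of lge_phase ---
  mk_lge <- phantom_masks(cfg, cfg$spacing_lge, cfg$lge_phase)
  lge_img <- array(0, dim = dim(mk_lge$myo))
  lge_img[mk_lge$blood] <- cfg$lge_blood
  lge_img[mk_lge$myo] <- cfg$lge_remote
  lge_img[mk_lge$infarct] <- cfg$lge_infarct
  lge <- image_stack(lge_img, cfg$spacing_lge, cfg$thickness,
                     contours = phantom_contours(cfg, cfg$lge_phase))
  lge <- add_rician_noise(lge, cfg$snr_lge, phantom_seed(cfg$seed, 9L),
                          reference = cfg$lge_infarct)

  # --- LGE-grid masks at the b0 phase (post-registration reference) ---
  mk_lge0 <- phantom_masks(cfg, cfg$spacing_lge, cfg$b0_phase)

  cine <- simulate_cine(cfg)

  # True displacement field: world points (n x 2, mm) at the b0-phase
  # position -> displacement (mm) to their lge-phase position.
  cfg_local <- cfg
  displacement_fun <- function(points, slice, phase = cfg_local$lge_phase) {
    dx <- points[, 1] - ctr[1]
    dy <- points[, 2] - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    alpha <- wrap360(atan2(dy, dx) * 180 / pi - cfg_local$reference_angle)
    ur <- radial_displacement(cfg_local, r, alpha, slice, phase)
    cbind(ur * dx / pmax(r, 1e-9), ur * dy / pmax(r, 1e-9))
  }

  max_s <- max(phase_factor(seq_len(cfg$n_phases) - 1L, cfg$n_phases))
  true_excursion <- function(alpha, slice) {
    excursion_profile(cfg_local, alpha, slice) * max_s
  }

  truth <- list(
    adc = image_stack(adc_true, cfg$spacing_dwi, cfg$thickness),
    myocardium = image_stack(mk$myo * 1, cfg$spacing_dwi, cfg$thickness),
    infarct = image_stack(mk$infarct * 1, cfg$spacing_dwi, cfg$thickness),
    myocardium_lge = image_stack(mk_lge0$myo * 1, cfg$spacing_lge, cfg$thickness),
    infarct_lge = image_stack(mk_lge0$infarct * 1, cfg$spacing_lge, cfg$thickness),
    infarct_lge_acquired = image_stack(mk_lge$infarct * 1, cfg$spacing_lge,
                                       cfg$thickness),
    displacement = displacement_fun,
    excursion = true_excursion,
    center = ctr,
    reference_angle = cfg$reference_angle,
    b0_phase = cfg$b0_phase,
    lge_phase = cfg$lge_phase,
    infarct_fraction = true_infarct_fraction(cfg)
  )

  structure(
    list(config = cfg, b0 = b0_noisy, b0_clean = b0, dwi = dwi,
         dwi_clean = dwi_clean, lge = lge, cine = cine, truth = truth),
    class = "phantom_study"
  )
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf(
    "<phantom_study> %d slices; infarct fraction %.1f%%; SNR %s; seed %s\n",
    n_slices(x$b0), 100 * x$truth$infarct_fraction,
    format(x$config$snr), format(x$config$seed)))
  invisible(x)
}

#' Write a phantom study to disk
#'
#' Writes one NIfTI volume per contrast and diffusion direction, label NIfTIs
#' for the ground-truth masks, a JSON sidecar with the true parameters, and
#' the YAML configuration used.
#'
#' @param study a `phantom_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_stack(study$b0, file.path(dir, "b0.nii.gz"))
  for (d in names(study$dwi)) {
    write_image_stack(study$dwi[[d]], file.path(dir, sprintf("dwi_%s.nii.gz", d)))
  }
  write_image_stack(study$lge, file.path(dir, "lge.nii.gz"))
  write_image_stack(study$truth$myocardium, file.path(dir, "truth_myocardium.nii.gz"))
  write_image_stack(study$truth$infarct, file.path(dir, "truth_infarct.nii.gz"))
  adc <- study$truth$adc
  adc$data[is.na(adc$data)] <- 0
  write_image_stack(adc, file.path(dir, "truth_adc.nii.gz"))
  cfg <- study$config
  cfg_list <- unclass(cfg)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  sidecar <- list(
    infarct_fraction = study$truth$infarct_fraction,
    reference_angle = study$truth$reference_angle,
    b0_phase = study$truth$b0_phase,
    lge_phase = study$truth$lge_phase,
    center_mm = study$truth$center,
    adc_remote = cfg$adc_remote,
    adc_infarct = cfg$adc_infarct,
    b_value = cfg$b_value
  )
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
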