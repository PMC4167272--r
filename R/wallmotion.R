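#' Chord-based regional wall motion
#'
#' Regional wall motion (RWM) is measured along evenly spaced virtual chords:
#' rays cast from a fixed LV centre through the endo- and epicardial
#' contours. Displacement of the endocardial intersection point along each
#' chord across the cine phases, relative to a reference phase, gives the
#' per-chord RWM; segments whose mean absolute displacement is at or below
#' 3 mm are classified akinetic.
#'
#' @name wallmotion
NULL

#' Define evenly spaced chords on a contour pair
#'
#' Casts `n` rays from the LV centre (the epicardial centroid by default) at
#' uniform angular spacing and intersects each with the endo- and epicardial
#' contours. Errors if the contours cross (endocardium outside epicardium
#' anywhere) or if a ray intersects a contour more than once.
#'
#' @param endo,epi closed contour matrices (world mm).
#' @param n number of chords (default 100).
#' @param center optional fixed LV centre (mm).
#' @return List with `angles` (deg), `endo_r`, `epi_r` (mm radii), `length`
#'   (chord lengths), and `center`.
#' @export
compute_chords <- function(endo, epi, n = 100, center = NULL) {
  ctr <- center %||% polygon_centroid(epi)
  angles <- seq(0, 360, length.out = n + 1L)[seq_len(n)]
  re <- ray_polygon_radius(endo, ctr, angles)
  rp <- ray_polygon_radius(epi, ctr, angles)
  if (any(re >= rp)) {
    stop_dwcmr("contours cross: endocardium reaches outside the epicardium")
  }
  list(angles = angles, endo_r = re, epi_r = rp, length = rp - re,
       center = ctr)
}

#' Per-chord wall displacement across the cine cycle
#'
#' For each slice, chords are defined on the reference-phase contours about a
#' fixed centre (the reference-phase epicardial centroid), and each chord's
#' displacement is the maximal excursion of the endocardial intersection
#' point along the chord over all phases, relative to the reference phase.
#' The fixed centre avoids motion cancelling against a drifting per-phase
#' centroid.
#'
#' @param cine a `cine_study`.
#' @param reference_phase 0-based reference phase (default 0, end-diastole).
#' @param n chords per slice (default 100).
#' @return A `chord_displacement_map`: per-slice `angles` (deg) and
#'   `displacement` (mm), plus `reference_phase` and `centers`.
#' @export
chord_displacement <- function(cine, reference_phase = 0L, n = 100) {
  np <- cine$n_phases
  if (reference_phase < 0 || reference_phase >= np) {
    stop_dwcmr("reference phase out of range")
  }
  nsl <- length(cine$contours[[1]])
  for (p in seq_len(np)) {
    if (length(cine$contours) < p || is.null(cine$contours[[p]]) ||
        length(cine$contours[[p]]) < nsl) {
      stop_dwcmr("missing contours for phase ", p - 1L)
    }
  }
  slices <- vector("list", nsl)
  centers <- vector("list", nsl)
  for (s in seq_len(nsl)) {
    ref <- cine$contours[[reference_phase + 1L]][[s]]
    ctr <- polygon_centroid(ref$epi)
    ch <- compute_chords(ref$endo, ref$epi, n = n, center = ctr)
    disp <- numeric(n)
    for (p in seq_len(np)) {
      rp <- ray_polygon_radius(cine$contours[[p]][[s]]$endo, ctr, ch$angles)
      disp <- pmax(disp, abs(rp - ch$endo_r))
    }
    slices[[s]] <- list(angles = ch$angles, displacement = disp,
                        endo_r = ch$endo_r, epi_r = ch$epi_r)
    centers[[s]] <- ctr
  }
  structure(list(slices = slices, n = n, reference_phase = reference_phase,
                 centers = centers),
            class = "chord_displacement_map")
}

#' @export
print.chord_displacement_map <- function(x, ...) {
  rng <- range(unlist(lapply(x$slices, `[[`, "displacement")))
  cat(sprintf(
    "<chord_displacement_map> %d slices x %d chords, displacement %.2f-%.2f mm\n",
    length(x$slices), x$n, rng[1], rng[2]))
  invisible(x)
}

#' Classify akinetic AHA segments from chord displacements
#'
#' A segment is akinetic when the mean absolute displacement of its chords
#' is at or below the cutoff (3 mm by default). Chord-to-segment assignment
#' must cover every chord.
#'
#' @param rwm a `chord_displacement_map`.
#' @param segment_labels per-slice list of integer vectors assigning each
#'   chord an AHA segment number 1-16 (see [aha_chord_segments()]).
#' @param cutoff akinesis cutoff in mm.
#' @return A [segment_score()] (modality `"RWM"`); segments with no chords
#'   (e.g. apical segments on a basal-slice-only map) score 0.
#' @export
classify_akinetic <- function(rwm, segment_labels, cutoff = 3) {
  if (length(segment_labels) != length(rwm$slices)) {
    stop_dwcmr("segment labels must be given for every slice")
  }
  disp <- unlist(lapply(rwm$slices, `[[`, "displacement"))
  lab <- unlist(segment_labels)
  if (length(lab) != length(disp) || anyNA(lab)) {
    stop_dwcmr("every chord needs a segment label")
  }
  means <- tapply(abs(disp), factor(lab, levels = 1:16), mean)
  score <- as.integer(!is.na(means) & means <= cutoff)
  segment_score(score, modality = "RWM")
}

#' Mean chord displacement over an angular sector
#'
#' Convenience summary used for infarct-zone vs remote wall-motion levels:
#' mean displacement of the chords of `slices` whose anatomical angle falls
#' in `[from, from + width)` degrees.
#'
#' @param rwm a `chord_displacement_map`.
#' @param from,width sector definition in anatomical (alpha) degrees.
#' @param reference_angle image-coordinate angle of the anatomical reference
#'   ray.
#' @param slices slice indices to pool (default: all).
#' @return List with `mean`, `sd`, `n`.
#' @export
sector_rwm <- function(rwm, from, width, reference_angle = 0,
                       slices = seq_along(rwm$slices)) {
  vals <- unlist(lapply(slices, function(s) {
    sl <- rwm$slices[[s]]
    alpha <- wrap360(sl$angles - reference_angle)
    sl$displacement[in_sector(alpha, from, width)]
  }))
  if (!length(vals)) stop_dwcmr("no chords in the requested sector")
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}
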