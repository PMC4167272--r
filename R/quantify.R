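#' Semi-automatic infarct quantification
#'
#' Two standard classifiers delineate hyperintense infarct on a map (an ADC
#' map or an LGE image), restricted to the LV myocardium:
#' the n-SD threshold criterion (voxels above the remote-region mean plus
#' `n_sd` standard deviations) and the FWHM region-growing criterion. Both
#' run identically on either modality; only the input image differs.
#'
#' @name quantify
NULL

new_infarct_mask <- function(mask_array, template, method, provenance,
                             myocardium) {
  structure(
    list(mask = image_stack(mask_array * 1, template$spacing, template$thickness),
         method = method, provenance = provenance,
         myocardium = as_mask_array(myocardium, template)),
    class = "infarct_mask"
  )
}

#' @export
print.infarct_mask <- function(x, ...) {
  cat(sprintf("<infarct_mask> method %s: %d voxels (%.1f%% of myocardium)\n",
              x$method, sum(x$mask$data),
              100 * sum(x$mask$data) / max(1, sum(x$myocardium))))
  invisible(x)
}

#' n-SD threshold infarct classifier
#'
#' Classifies as infarct every myocardial voxel whose value exceeds
#' `mean(remote) + n_sd * SD(remote)`, the remote statistics being taken over
#' a manually (or programmatically) selected remote region of interest.
#' With a degenerate remote SD of zero the cutoff reduces to the remote
#' mean (strictly-greater comparison).
#'
#' @param map an [image_stack()] (ADC map or LGE image); `NA` voxels are
#'   never classified and are excluded from the remote statistics.
#' @param remote_roi remote region mask (subset of the myocardium).
#' @param myocardium myocardium mask.
#' @param n_sd standard-deviation multiplier (default 6).
#' @return An `infarct_mask`.
#' @export
threshold_classify <- function(map, remote_roi, myocardium, n_sd = 6) {
  myo <- as_mask_array(myocardium, map)
  roi <- as_mask_array(remote_roi, map)
  if (any(roi & !myo)) stop_dwcmr("remote ROI must lie within the myocardium")
  vals <- map$data[roi]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop_dwcmr("remote ROI is empty")
  if (length(vals) == 1L) {
    stop_dwcmr("remote ROI has a single voxel; its SD is undefined")
  }
  cutoff <- mean(vals) + n_sd * stats::sd(vals)
  m <- myo & !is.na(map$data) & map$data > cutoff
  out <- new_infarct_mask(m, map, "threshold",
                          list(n_sd = n_sd, cutoff = cutoff,
                               remote_mean = mean(vals),
                               remote_sd = stats::sd(vals)),
                          myo)
  out
}

#' FWHM region-growing infarct classifier
#'
#' The two-stage full-width-half-maximum rule: (1) a "seed region" is grown
#' (4-connectivity, in-plane) from a manually placed seed voxel over
#' myocardial voxels with value >= 50% of the seed's value; (2) the maximum
#' of that seed region defines the final cutoff, and the final mask contains
#' the myocardial voxels with value >= 50% of that maximum, restricted to
#' connected components that intersect the seed region (so remote islands
#' that merely clear the cutoff are not picked up). Growth never crosses
#' slices; pass one seed per lesion-bearing slice (the masks are unioned).
#'
#' @param map an [image_stack()].
#' @param seed_voxel integer vector `c(i, j, slice)`, or a matrix of such
#'   rows for multiple seeds.
#' @param myocardium myocardium mask containing every seed.
#' @param fraction half-maximum fraction (default 0.5).
#' @return An `infarct_mask`.
#' @export
fwhm_classify <- function(map, seed_voxel, myocardium, fraction = 0.5) {
  myo <- as_mask_array(myocardium, map)
  seeds <- if (is.matrix(seed_voxel)) seed_voxel else matrix(seed_voxel, nrow = 1)
  if (ncol(seeds) != 3L) stop_dwcmr("seeds must be (i, j, slice) triples")
  final <- array(FALSE, dim = dim(map$data))
  nx <- dim(map$data)[1]
  for (r in seq_len(nrow(seeds))) {
    i <- seeds[r, 1]; j <- seeds[r, 2]; s <- seeds[r, 3]
    if (!myo[i, j, s]) stop_dwcmr("seed voxel lies outside the myocardium")
    vals <- array(map$data[, , s], dim = dim(map$data)[1:2])
    msl <- array(myo[, , s], dim = dim(map$data)[1:2]) & !is.na(vals)
    seed_val <- vals[i, j]
    if (is.na(seed_val)) stop_dwcmr("seed voxel has an undefined map value")
    lin <- (j - 1L) * nx + i
    grow <- msl & !is.na(vals) & vals >= fraction * seed_val
    seed_region <- grow_region(grow, lin)
    peak <- max(vals[seed_region])
    cond <- msl & vals >= fraction * peak
    lab <- label_components(cond)
    keep <- unique(lab[seed_region & cond])
    keep <- keep[keep != 0L]
    final[, , s] <- final[, , s] | (lab %in% keep & cond)
  }
  new_infarct_mask(final, map, "fwhm",
                   list(seeds = seeds, fraction = fraction), myo)
}

#' Infarct volume as a percentage of the imaged LV myocardium
#'
#' `100 * infarct voxels / myocardial voxels` over the acquired slices (the
#' constant voxel volume cancels; it can be supplied for documentation).
#'
#' @param mask an `infarct_mask` (or plain mask).
#' @param myocardium myocardium mask.
#' @param voxel_vol optional voxel volume in mm^3 (unused in the ratio).
#' @return Percentage in `[0, 100]`.
#' @export
infarct_volume_pct <- function(mask, myocardium, voxel_vol = NULL) {
  m <- if (inherits(mask, "infarct_mask")) mask$mask$data != 0 else
    as_mask_array(mask)
  myo <- as_mask_array(myocardium)
  if (!sum(myo)) stop_dwcmr("myocardium mask is empty")
  if (any(m & !myo)) stop_dwcmr("infarct mask extends outside the myocardium")
  100 * sum(m) / sum(myo)
}

#' Transmurality of each connected infarct
#'
#' An infarct component is completely transmural if, within its angular span
#' about the LV centre, the mask spans the wall from endocardium to
#' epicardium along every radial ray (to within a one-voxel tolerance at
#' each surface).
#'
#' @param mask an `infarct_mask` or binary stack.
#' @param contours per-slice list of `endo` / `epi` contour matrices
#'   (world mm), as carried by phantom images.
#' @param center optional LV centre (mm); defaults to the epicardial
#'   centroid per slice.
#' @param ray_step angular sampling of the span (degrees).
#' @return Data frame with one row per connected infarct component:
#'   `slice`, `component`, `n_voxels`, `transmural`. Zero rows if the mask
#'   is empty.
#' @export
transmurality <- function(mask, contours, center = NULL, ray_step = 2) {
  stk <- if (inherits(mask, "infarct_mask")) mask$mask else mask
  arr <- as_mask_array(stk)
  spacing <- stk$spacing
  tol <- max(spacing)
  res <- list()
  for (s in seq_len(dim(arr)[3])) {
    msl <- array(arr[, , s], dim = dim(arr)[1:2])
    if (!any(msl)) next
    endo <- contours[[s]]$endo
    epi <- contours[[s]]$epi
    ctr <- center %||% polygon_centroid(epi)
    lab <- label_components(msl)
    for (cmp in seq_len(max(lab))) {
      vox <- which(lab == cmp, arr.ind = TRUE)
      px <- (vox[, 1] - 0.5) * spacing[1]
      py <- (vox[, 2] - 0.5) * spacing[2]
      ang <- angle_deg(px, py, ctr[1], ctr[2])
      span <- angular_span(ang)
      # trim span edges by roughly one voxel of arc to avoid partial columns
      rmid <- mean(sqrt((px - ctr[1])^2 + (py - ctr[2])^2))
      trim <- max(ray_step / 2, (max(spacing) / rmid) * 180 / pi)
      width <- span$width - 2 * trim
      ok <- TRUE
      if (width > 0) {
        rays <- wrap360(span$from + trim + seq(0, width, by = ray_step))
        for (a in rays) {
          re <- ray_polygon_radius(endo, ctr, a, require_unique = FALSE)
          rp <- ray_polygon_radius(epi, ctr, a, require_unique = FALSE)
          rr <- seq(re + tol, rp - tol, by = min(spacing) / 2)
          if (!length(rr)) next
          xi <- pmin(pmax(round(ctr[1] / spacing[1] + rr * cos(a * pi / 180) / spacing[1] + 0.5), 1), nrow(msl))
          yi <- pmin(pmax(round(ctr[2] / spacing[2] + rr * sin(a * pi / 180) / spacing[2] + 0.5), 1), ncol(msl))
          if (!all(msl[cbind(xi, yi)])) { ok <- FALSE; break }
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        slice = s, component = cmp, n_voxels = nrow(vox), transmural = ok)
    }
  }
  if (!length(res)) {
    return(data.frame(slice = integer(0), component = integer(0),
                      n_voxels = integer(0), transmural = logical(0)))
  }
  do.call(rbind, res)
}

# Angular span of a set of angles (deg): the arc not containing the largest
# gap. Returns list(from, width).
angular_span <- function(ang) {
  a <- sort(wrap360(ang))
  if (length(a) == 1L) return(list(from = a, width = 0))
  gaps <- c(diff(a), a[1] + 360 - a[length(a)])
  g <- which.max(gaps)
  from <- if (g == length(a)) a[1] else a[g + 1L]
  list(from = from, width = 360 - gaps[g])
}
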