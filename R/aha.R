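#' AHA 16-segment model for a three-slice short-axis protocol
#'
#' The basal and mid short-axis slices are divided into six 60-degree
#' sectors (AHA segments 1-6 and 7-12) and the apical slice into four
#' 90-degree sectors (segments 13-16), numbered counter-clockwise from the
#' anterior reference ray. The 17th apex-cap segment is not acquired in a
#' three-slice protocol and is not scored.
#'
#' @name aha
NULL

aha_levels <- c("basal", "mid", "apical")

# Segment numbers for anatomical angles alpha (deg) at one slice level.
aha_segment_of_alpha <- function(alpha, level) {
  level <- match.arg(level, aha_levels)
  a <- wrap360(alpha)
  switch(level,
    basal = 1L + (floor(a / 60) %% 6L),
    mid = 7L + (floor(a / 60) %% 6L),
    apical = 13L + (floor(a / 90) %% 4L)
  )
}

#' Assign AHA segment labels to a myocardium slice
#'
#' Builds the per-voxel segment label map for one slice: 6 equal sectors
#' (basal or mid level) or 4 (apical level), numbered in the standard AHA
#' order starting at the anterior reference ray, with global numbering
#' (basal 1-6, mid 7-12, apical 13-16).
#'
#' @param level `"basal"`, `"mid"` or `"apical"`.
#' @param myocardium logical/0-1 matrix for the slice, or an
#'   [image_stack()] together with `slice`.
#' @param reference_angle image-coordinate angle (deg, CCW from +x) of the
#'   anterior reference ray; required.
#' @param spacing in-plane pixel spacing (mm); taken from the stack if one
#'   is given.
#' @param center optional LV centre (mm); defaults to the myocardium
#'   centroid.
#' @param slice slice index when `myocardium` is a stack.
#' @return Integer matrix: 0 outside the myocardium, the AHA segment number
#'   inside.
#' @export
assign_segments <- function(level, myocardium, reference_angle,
                            spacing = NULL, center = NULL, slice = 1L) {
  if (missing(reference_angle) || is.null(reference_angle)) {
    stop_dwcmr("the anterior reference angle is required")
  }
  if (inherits(myocardium, "image_stack")) {
    spacing <- myocardium$spacing
    myocardium <- myocardium$data[, , slice]
  }
  if (is.null(spacing)) stop_dwcmr("`spacing` is required with a bare matrix")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  m <- myocardium != 0 & !is.na(myocardium)
  if (!any(m)) stop_dwcmr("myocardium mask is empty")
  idx <- which(m, arr.ind = TRUE)
  px <- (idx[, 1] - 0.5) * spacing[1]
  py <- (idx[, 2] - 0.5) * spacing[2]
  ctr <- center %||% c(mean(px), mean(py))
  alpha <- wrap360(angle_deg(px, py, ctr[1], ctr[2]) - reference_angle)
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[idx] <- aha_segment_of_alpha(alpha, level)
  lab
}

#' Segment labels for all slices of a stack
#'
#' Convenience wrapper building the full label stack for the standard
#' base/mid/apex ordering.
#'
#' @param myocardium an [image_stack()] myocardium mask (3 slices).
#' @param reference_angle anterior reference angle (deg).
#' @param levels slice levels, default `c("basal", "mid", "apical")`.
#' @param center optional LV centre (mm).
#' @return Integer array of segment labels.
#' @export
assign_segments_stack <- function(myocardium, reference_angle,
                                  levels = aha_levels, center = NULL) {
  d <- dim(myocardium$data)
  if (d[3] != length(levels)) stop_dwcmr("one level per slice is required")
  lab <- array(0L, d)
  for (s in seq_len(d[3])) {
    lab[, , s] <- assign_segments(levels[s], myocardium, reference_angle,
                                  center = center, slice = s)
  }
  lab
}

#' AHA segment of each chord
#'
#' @param angles chord angles in image coordinates (deg).
#' @param level slice level.
#' @param reference_angle anterior reference angle (deg).
#' @return Integer vector of AHA segment numbers.
#' @export
aha_chord_segments <- function(angles, level, reference_angle) {
  aha_segment_of_alpha(wrap360(angles - reference_angle), level)
}

#' Binary 16-segment score vector
#'
#' @param values length-16 vector of 0/1 values, ordered basal 1-6, mid
#'   7-12, apical 13-16.
#' @param modality optional tag (`"ADC"`, `"LGE"`, `"RWM"`).
#' @param reviewer optional reviewer tag.
#' @return A `segment_score` integer vector.
#' @export
segment_score <- function(values, modality = NA_character_,
                          reviewer = NA_character_) {
  v <- as.integer(values)
  if (length(v) != 16L || anyNA(v) || !all(v %in% 0:1)) {
    stop_dwcmr("a segment score is 16 binary values")
  }
  structure(v, modality = modality, reviewer = reviewer,
            class = "segment_score")
}

#' @export
print.segment_score <- function(x, ...) {
  cat(sprintf("<segment_score>%s positives: %s\n",
              if (is.na(attr(x, "modality"))) "" else
                paste0(" [", attr(x, "modality"), "]"),
              if (sum(x)) paste(which(x == 1L), collapse = ", ") else "none"))
  invisible(x)
}

#' Score segments from an infarct mask (any-voxel rule)
#'
#' A segment is positive if it contains at least one masked voxel.
#'
#' @param mask an `infarct_mask` or binary stack.
#' @param labels segment label array from [assign_segments_stack()].
#' @param modality,reviewer tags carried on the score.
#' @return A [segment_score()].
#' @export
score_segments <- function(mask, labels, modality = NA_character_,
                           reviewer = NA_character_) {
  m <- if (inherits(mask, "infarct_mask")) mask$mask$data != 0 else
    as_mask_array(mask)
  if (!identical(dim(m), dim(labels))) {
    stop_dwcmr("mask and label geometry differ")
  }
  pos <- tabulate(labels[m], nbins = 16L) > 0L
  segment_score(as.integer(pos), modality = modality, reviewer = reviewer)
}
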