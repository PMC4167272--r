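#' Two-point monoexponential ADC fit
#'
#' Per-voxel apparent diffusion coefficient from a b0 stack and one
#' diffusion-weighted stack, solving `Sb = S0 * exp(-b * ADC)`:
#' `ADC = ln(S0 / Sb) / b`, reported in um^2/ms (1 um^2/ms = 1e-3 mm^2/s, so
#' the fit in mm^2/s is scaled by 1e3 once here). Voxels with non-positive
#' signal in either input, or with `Sb > S0` (a negative, non-physical fit),
#' are flagged invalid and excluded from downstream regional means rather
#' than clamped, which would bias those means.
#'
#' @param b0 non-diffusion-weighted [image_stack()].
#' @param bdw diffusion-weighted [image_stack()] of matching geometry.
#' @param b b-value in s/mm^2 (> 0).
#' @return An `adc_map`: an [image_stack()] of ADC values (um^2/ms, `NA`
#'   where invalid) with fields `valid` (logical array), `b` and
#'   `directions`.
#' @export
fit_adc <- function(b0, bdw, b) {
  check_same_geometry(b0, bdw, "b0 and diffusion-weighted images")
  if (!is.numeric(b) || length(b) != 1L || b <= 0) {
    stop_dwcmr("`b` must be a positive b-value in s/mm^2")
  }
  s0 <- b0$data
  sb <- bdw$data
  valid <- s0 > 0 & sb > 0 & sb <= s0
  adc <- array(NA_real_, dim = dim(s0))
  adc[valid] <- log(s0[valid] / sb[valid]) / b * 1e3
  out <- image_stack(adc, b0$spacing, b0$thickness)
  out$valid <- valid
  out$b <- b
  out$directions <- 1L
  class(out) <- c("adc_map", class(out))
  out
}

#' Trace ADC from three orthogonal directions
#'
#' Voxelwise arithmetic mean `ADC = (ADC_x + ADC_y + ADC_z) / 3`; a voxel is
#' valid only where all three inputs are valid.
#'
#' @param adc_x,adc_y,adc_z `adc_map`s of matching geometry and b-value.
#' @return An `adc_map` with `directions = 3`.
#' @export
trace_adc <- function(adc_x, adc_y, adc_z) {
  check_same_geometry(adc_x, adc_y, "ADC maps")
  check_same_geometry(adc_x, adc_z, "ADC maps")
  if (!isTRUE(all.equal(adc_x$b, adc_y$b)) || !isTRUE(all.equal(adc_x$b, adc_z$b))) {
    stop_dwcmr("ADC maps were fitted at different b-values")
  }
  valid <- adc_x$valid & adc_y$valid & adc_z$valid
  adc <- array(NA_real_, dim = dim(adc_x$data))
  adc[valid] <- (adc_x$data[valid] + adc_y$data[valid] + adc_z$data[valid]) / 3
  out <- image_stack(adc, adc_x$spacing, adc_x$thickness)
  out$valid <- valid
  out$b <- adc_x$b
  out$directions <- 3L
  class(out) <- c("adc_map", class(out))
  out
}

#' Mean and SD of a map over a region
#'
#' Regional summary over the masked voxels; for an `adc_map`, voxels flagged
#' invalid are excluded.
#'
#' @param map an [image_stack()] (typically an `adc_map`).
#' @param mask logical/0-1 array or `image_stack` of the same geometry.
#' @return List with `mean`, `sd`, and `n` (voxels used).
#' @export
mean_region_adc <- function(map, mask) {
  m <- as_mask_array(mask, map)
  if (!is.null(map$valid)) m <- m & map$valid
  vals <- map$data[m]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop_dwcmr("region is empty (or entirely invalid)")
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

# Coerce a mask argument (image_stack, numeric or logical array) to a logical
# array matching `ref`.
as_mask_array <- function(mask, ref = NULL) {
  if (inherits(mask, "image_stack")) {
    if (!is.null(ref) && inherits(ref, "image_stack")) {
      check_same_geometry(mask, ref, "mask and map")
    }
    mask <- mask$data
  }
  if (!is.null(ref)) {
    rd <- if (inherits(ref, "image_stack")) dim(ref$data) else dim(ref)
    if (!identical(dim(mask), rd)) stop_dwcmr("mask geometry does not match map")
  }
  array(mask != 0 & !is.na(mask), dim = dim(mask))
}
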