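#' Short-axis image stack
#'
#' The basic carrier for all volumetric data in the package: a small stack of
#' short-axis slices (typically base / mid / apex) of a single scalar contrast
#' (b0, a diffusion-weighted image, an ADC map, an LGE image, a binary mask),
#' with in-plane pixel spacing and slice thickness in millimetres.
#'
#' World coordinates are in mm: a voxel at array index `(i, j, s)` has
#' in-plane centre `x = (i - 0.5) * spacing[1]`, `y = (j - 0.5) * spacing[2]`.
#' Slice 1 is the most basal slice by default.
#'
#' @param data numeric 3-D array `(nx, ny, nslices)` (a matrix is promoted to
#'   a single slice).
#' @param spacing length-2 numeric, in-plane pixel spacing in mm.
#' @param thickness slice thickness in mm.
#' @param contours optional per-slice contour list (each element a list with
#'   `endo` and `epi` n x 2 matrices of world mm coordinates), carried along
#'   for contour-based operations such as phase matching.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, spacing, thickness = 6, contours = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) {
    stop_dwcmr("`data` must be a (nx, ny, nslices) array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_dwcmr("`spacing` must be two positive pixel sizes in mm")
  }
  if (!is.numeric(thickness) || thickness <= 0) {
    stop_dwcmr("`thickness` must be a positive slice thickness in mm")
  }
  structure(
    list(data = data, spacing = spacing, thickness = thickness,
         contours = contours),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d x %d slices, %.3g x %.3g mm in-plane, %.3g mm thick\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$thickness))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g]%s\n", rng[1], rng[2],
              if (is.null(x$contours)) "" else ", contours attached"))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_slices <- function(x) dim(x$data)[3]

#' Check that two stacks share grid geometry
#'
#' @param a,b `image_stack` objects.
#' @param what label used in the error message.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @keywords internal
check_same_geometry <- function(a, b, what = "images") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      abs(a$thickness - b$thickness) > 1e-9) {
    stop_dwcmr("geometry mismatch between ", what,
               " (grid, spacing, and thickness must agree)")
  }
  invisible(TRUE)
}

# World mm coordinates of voxel centres for one slice of a stack.
grid_coords <- function(stack) {
  d <- dim(stack$data)
  list(
    x = (seq_len(d[1]) - 0.5) * stack$spacing[1],
    y = (seq_len(d[2]) - 0.5) * stack$spacing[2]
  )
}

# Voxel volume in mm^3.
voxel_volume <- function(stack) prod(stack$spacing) * stack$thickness

#' Write / read an image stack as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} used by the file-based interfaces; the
#' pixel dimensions carry the in-plane spacing and slice thickness.
#'
#' @param stack an `image_stack`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- c(stack$spacing, stack$thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  image_stack(arr, spacing = pd[1:2], thickness = pd[3])
}
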