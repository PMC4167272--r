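#' Two-step cine-based co-registration
#'
#' The LGE image is never registered to the ADC map directly: the cardiac
#' phase of each acquisition is identified on the cine series, the two cine
#' phases are registered with a non-rigid B-spline point-based transform, and
#' that transform is applied to the LGE image. This keeps any registration
#' error independent of the infarct delineation being compared.
#'
#' @name register
NULL

# ---- phase matching --------------------------------------------------------

#' Select the cine phase matching a target acquisition
#'
#' Automated surrogate for visual phase screening: returns the cine phase
#' minimizing the mean symmetric contour-to-contour distance (endo and epi,
#' all slices) between the target's contours and each phase's contours. The
#' metric is intensity-independent, so it works across contrasts. Ties break
#' toward the earlier phase.
#'
#' @param cine a `cine_study` (see [simulate_cine()]).
#' @param target an [image_stack()] carrying `contours`, or a per-slice
#'   contour list of the same shape as `cine$contours[[p]]`.
#' @return The 0-based phase index.
#' @export
select_matching_phase <- function(cine, target) {
  if (!length(cine$contours)) stop_dwcmr("cine study has no phases")
  tc <- if (inherits(target, "image_stack")) target$contours else target
  if (is.null(tc)) stop_dwcmr("target carries no contours to match on")
  dis <- vapply(cine$contours, function(pc) {
    d <- mapply(function(a, b) {
      (symmetric_contour_distance(a$endo, b$endo) +
       symmetric_contour_distance(a$epi, b$epi)) / 2
    }, tc, pc)
    mean(d)
  }, numeric(1))
  which.min(dis) - 1L
}

# Mean symmetric nearest-point distance between two point sets (n x 2).
symmetric_contour_distance <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

#' Sample contour landmarks at equal arc length
#'
#' Resamples a closed contour polygon to `n` points at equal arc length,
#' starting from the point nearest angle 0 about the contour centroid; used
#' to build corresponding landmark sets from two phases of the same contour.
#'
#' @param contour n x 2 matrix of contour points (ordered along the contour).
#' @param n number of landmarks.
#' @return An n x 2 matrix.
#' @export
contour_landmarks <- function(contour, n = 50) {
  p <- rbind(contour, contour[1, ])
  seglen <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  cbind(stats::approx(s, p[, 1], xout = target)$y,
        stats::approx(s, p[, 2], xout = target)$y)
}

# ---- cubic B-spline free-form deformation ---------------------------------

# Uniform cubic B-spline weights at fractional position u in [0, 1).
bspline_weights <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# 1-D basis lookup: indices (n x 4, 1-based into a lattice with 3 padding
# points) and weights for coordinates x (mm) on a lattice of spacing h
# starting at `origin`. Coordinates outside the lattice are clamped.
bspline_basis_1d <- function(x, h, origin, n_ctrl) {
  t <- (x - origin) / h
  t <- pmin(pmax(t, 0), n_ctrl - 3 - 1e-9)
  i <- floor(t)
  u <- t - i
  idx <- outer(i, 0:3, "+") + 1L   # controls i .. i+3, 1-based
  list(idx = idx, w = bspline_weights(u))
}

new_bspline_lattice <- function(domain, spacing) {
  # domain = c(xmin, xmax, ymin, ymax) in mm
  ncx <- ceiling((domain[2] - domain[1]) / spacing) + 3L
  ncy <- ceiling((domain[4] - domain[3]) / spacing) + 3L
  list(origin = c(domain[1], domain[3]), spacing = spacing,
       ncx = ncx, ncy = ncy)
}

# Dense design matrix mapping vectorized control values (ncx*ncy) to values
# at scattered points.
bspline_design <- function(points, lat) {
  bx <- bspline_basis_1d(points[, 1], lat$spacing, lat$origin[1], lat$ncx)
  by <- bspline_basis_1d(points[, 2], lat$spacing, lat$origin[2], lat$ncy)
  n <- nrow(points)
  A <- matrix(0, n, lat$ncx * lat$ncy)
  for (a in 1:4) {
    for (b in 1:4) {
      k <- (by$idx[, b] - 1L) * lat$ncx + bx$idx[, a]
      A[cbind(seq_len(n), k)] <- A[cbind(seq_len(n), k)] + bx$w[, a] * by$w[, b]
    }
  }
  A
}

# Discrete bending-energy penalty matrix on the control lattice.
bending_penalty <- function(lat) {
  d2 <- function(n) {
    if (n < 3) return(matrix(0, 0, n))
    D <- matrix(0, n - 2, n)
    for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
    D
  }
  d1 <- function(n) {
    if (n < 2) return(matrix(0, 0, n))
    D <- matrix(0, n - 1, n)
    for (i in seq_len(n - 1)) D[i, i:(i + 1)] <- c(-1, 1)
    D
  }
  Ix <- diag(lat$ncx); Iy <- diag(lat$ncy)
  Dxx <- kronecker(Iy, d2(lat$ncx))
  Dyy <- kronecker(d2(lat$ncy), Ix)
  Dxy <- kronecker(d1(lat$ncy), d1(lat$ncx))
  crossprod(Dxx) + crossprod(Dyy) + 2 * crossprod(Dxy)
}

#' Fit a B-spline transform to corresponding landmarks
#'
#' Penalized least-squares fit of a per-slice cubic B-spline free-form
#' deformation mapping source landmarks onto destination landmarks, with a
#' discrete bending-energy penalty on the control lattice. The fitted
#' displacement field is C2-smooth by construction and is the identity when
#' all control displacements are zero.
#'
#' @param points_src,points_dst corresponding landmarks: n x 2 matrices (mm),
#'   or lists of such matrices (one per slice).
#' @param grid_spacing control-point spacing (mm).
#' @param lambda bending-energy regularization weight (>= 0).
#' @param domain optional c(xmin, xmax, ymin, ymax) the transform must cover
#'   (e.g. the extent of an image it will be applied to); defaults to the
#'   landmark bounding box plus one lattice cell.
#' @return A `bspline_transform` with per-slice control lattices and a
#'   `residuals` field (per-slice landmark RMSE, mm).
#' @export
fit_bspline <- function(points_src, points_dst, grid_spacing = 25,
                        lambda = 1e-3, domain = NULL) {
  if (is.matrix(points_src)) points_src <- list(points_src)
  if (is.matrix(points_dst)) points_dst <- list(points_dst)
  if (length(points_src) != length(points_dst)) {
    stop_dwcmr("source and destination landmark lists differ in length")
  }
  all_pts <- do.call(rbind, c(points_src, points_dst))
  if (is.null(domain)) {
    domain <- c(min(all_pts[, 1]) - grid_spacing, max(all_pts[, 1]) + grid_spacing,
                min(all_pts[, 2]) - grid_spacing, max(all_pts[, 2]) + grid_spacing)
  }
  lat <- new_bspline_lattice(domain, grid_spacing)
  P <- bending_penalty(lat)
  per_slice <- vector("list", length(points_src))
  rmse <- numeric(length(points_src))
  for (s in seq_along(points_src)) {
    src <- points_src[[s]]
    dst <- points_dst[[s]]
    if (nrow(src) != nrow(dst)) {
      stop_dwcmr("slice ", s, ": landmark lists differ in length")
    }
    if (nrow(src) < 4) {
      stop_dwcmr("slice ", s, ": at least 4 landmark pairs are required")
    }
    if (min(svd(scale(src, scale = FALSE))$d) < 1e-8 * max(1, max(abs(src)))) {
      stop_dwcmr("slice ", s, ": landmarks are collinear (degenerate fit)")
    }
    A <- bspline_design(src, lat)
    d <- dst - src
    if (lambda == 0) {
      # minimum-norm exact least squares: fitted landmark displacements are
      # untouched by the lattice null space
      sv <- svd(A)
      keep <- sv$d > max(sv$d) * 1e-10
      coef <- sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% d) / sv$d[keep])
    } else {
      AtA <- crossprod(A) + lambda * P
      # small ridge keeps unsupported lattice corners determined
      diag(AtA) <- diag(AtA) + 1e-10
      coef <- solve(AtA, crossprod(A, d))
    }
    fitted <- A %*% coef
    rmse[s] <- sqrt(mean(rowSums((fitted - d)^2)))
    per_slice[[s]] <- list(cx = matrix(coef[, 1], lat$ncx, lat$ncy),
                           cy = matrix(coef[, 2], lat$ncx, lat$ncy))
  }
  structure(list(lattice = lat, slices = per_slice, lambda = lambda,
                 residuals = rmse),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf(
    "<bspline_transform> %d slice(s), %d x %d control points @ %.3g mm, landmark RMSE %s mm\n",
    length(x$slices), x$lattice$ncx, x$lattice$ncy, x$lattice$spacing,
    paste(sprintf("%.3g", x$residuals), collapse = "/")))
  invisible(x)
}

#' Evaluate a B-spline transform's displacement field
#'
#' @param xfm a `bspline_transform`.
#' @param points n x 2 matrix of world coordinates (mm).
#' @param slice slice index.
#' @return n x 2 matrix of displacements (mm).
#' @export
eval_bspline <- function(xfm, points, slice = 1L) {
  lat <- xfm$lattice
  bx <- bspline_basis_1d(points[, 1], lat$spacing, lat$origin[1], lat$ncx)
  by <- bspline_basis_1d(points[, 2], lat$spacing, lat$origin[2], lat$ncy)
  cx <- xfm$slices[[slice]]$cx
  cy <- xfm$slices[[slice]]$cy
  ux <- numeric(nrow(points))
  uy <- numeric(nrow(points))
  for (a in 1:4) {
    for (b in 1:4) {
      k <- cbind(bx$idx[, a], by$idx[, b])
      w <- bx$w[, a] * by$w[, b]
      ux <- ux + w * cx[k]
      uy <- uy + w * cy[k]
    }
  }
  cbind(ux, uy)
}

#' Bending energy of a fitted transform
#'
#' Discrete bending energy (sum of squared second differences of the control
#' lattice, both directions plus twice the cross term) summed over slices;
#' increasing the regularization weight in [fit_bspline()] monotonically
#' decreases it.
#'
#' @param xfm a `bspline_transform`.
#' @return Non-negative scalar.
#' @export
bending_energy <- function(xfm) {
  P <- bending_penalty(xfm$lattice)
  sum(vapply(xfm$slices, function(s) {
    v1 <- as.numeric(s$cx); v2 <- as.numeric(s$cy)
    as.numeric(crossprod(v1, P %*% v1) + crossprod(v2, P %*% v2))
  }, numeric(1)))
}

#' Apply a transform to an image stack (backward warp)
#'
#' Resamples `image` through the transform: the output voxel at world
#' position `x` takes the value of the input at `x + u(x)`. Used with a
#' transform fitted from target-phase landmarks to source-phase landmarks,
#' this pulls the source image into the target geometry. Out-of-field
#' samples are filled with `background`.
#'
#' @param image an [image_stack()].
#' @param xfm a `bspline_transform` with as many slices as the image.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @param background fill value.
#' @return A resampled [image_stack()].
#' @export
apply_transform <- function(image, xfm, interpolation = c("linear", "nearest"),
                            background = 0) {
  interpolation <- match.arg(interpolation)
  if (length(xfm$slices) != n_slices(image)) {
    stop_dwcmr("transform and image disagree on slice count")
  }
  g <- grid_coords(image)
  nx <- length(g$x); ny <- length(g$y)
  pts <- cbind(rep(g$x, times = ny), rep(g$y, each = nx))
  out <- image
  for (s in seq_len(n_slices(image))) {
    u <- eval_bspline(xfm, pts, s)
    sx <- pts[, 1] + u[, 1]
    sy <- pts[, 2] + u[, 2]
    out$data[, , s] <- matrix(
      sample_slice(image$data[, , s], sx, sy, image$spacing,
                   background, interpolation),
      nx, ny)
  }
  out$contours <- NULL
  out
}

# Bilinear / nearest sampling of one slice at world mm positions.
sample_slice <- function(img, sx, sy, spacing, background, method) {
  fx <- sx / spacing[1] + 0.5   # voxel index coordinates (centre = integer)
  fy <- sy / spacing[2] + 0.5
  nx <- nrow(img); ny <- ncol(img)
  if (method == "nearest") {
    ix <- round(fx); iy <- round(fy)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    val <- rep(background, length(sx))
    val[ok] <- img[cbind(ix[ok], iy[ok])]
    return(val)
  }
  x0 <- floor(fx); y0 <- floor(fy)
  tx <- fx - x0; ty <- fy - y0
  val <- rep(background, length(sx))
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  if (any(ok)) {
    i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
    i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
    val[ok] <- img[i00] * (1 - tx[ok]) * (1 - ty[ok]) +
               img[i10] * tx[ok] * (1 - ty[ok]) +
               img[i01] * (1 - tx[ok]) * ty[ok] +
               img[i11] * tx[ok] * ty[ok]
  }
  val
}

#' Serialize a B-spline transform to JSON
#'
#' @param xfm a `bspline_transform`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transform <- function(xfm, path) {
  jsonlite::write_json(
    list(lattice = xfm$lattice, lambda = xfm$lambda,
         residuals = xfm$residuals,
         slices = lapply(xfm$slices, function(s) {
           list(cx = as.numeric(s$cx), cy = as.numeric(s$cy))
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
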