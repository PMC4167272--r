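# Shared 2-D geometry utilities: ray-polygon intersection and in-plane
# connected-component labelling.

# Centroid of a polygon's vertices (adequate for the near-circular LV
# contours used here).
polygon_centroid <- function(poly) colMeans(poly)

# Radial distance from `center` to a closed polygon along rays at
# `angles_deg` (degrees, CCW from +x). The polygon is treated as implicitly
# closed. Errors if a ray misses the polygon or crosses it more than twice
# (self-intersecting / not star-shaped about the centre), unless
# `require_unique = FALSE`, in which case the nearest crossing is returned.
ray_polygon_radius <- function(poly, center, angles_deg,
                               require_unique = TRUE) {
  p <- rbind(poly, poly[1, ])
  ax <- p[-nrow(p), 1] - center[1]; ay <- p[-nrow(p), 2] - center[2]
  bx <- p[-1, 1] - center[1];       by <- p[-1, 2] - center[2]
  ex <- bx - ax; ey <- by - ay
  th <- angles_deg * pi / 180
  out <- numeric(length(th))
  for (k in seq_along(th)) {
    dx <- cos(th[k]); dy <- sin(th[k])
    # solve a + t e = r d for each edge, keeping 0 <= t < 1 and r > 0
    den <- ex * dy - ey * dx
    ok <- abs(den) > 1e-12
    t <- rep(NA_real_, length(ex))
    t[ok] <- (ay[ok] * dx - ax[ok] * dy) / den[ok]
    # lower tolerance keeps rays that pass exactly through a vertex
    hit <- ok & t >= -1e-9 & t < 1
    r <- if (abs(dx) >= 0.5) {
      (ax[hit] + t[hit] * ex[hit]) / dx
    } else {
      (ay[hit] + t[hit] * ey[hit]) / dy
    }
    r <- r[r > 1e-9]
    if (!length(r)) {
      stop_dwcmr("a ray from the centre does not intersect the contour; ",
                 "contour may be open or the centre outside it")
    }
    if (require_unique && length(r) > 1 && diff(range(r)) > 1e-6) {
      stop_dwcmr("a ray intersects the contour more than once; ",
                 "contour is not star-shaped about the centre")
    }
    out[k] <- min(r)
  }
  out
}

# 4-connected component labelling of one logical slice. Returns an integer
# matrix (0 = background).
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nextlab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cur - 1L) %% nx) + 1L
      j <- ((cur - 1L) %/% nx) + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= nx && nb[2] >= 1L && nb[2] <= ny) {
          lin <- (nb[2] - 1L) * nx + nb[1]
          if (mask[lin] && lab[lin] == 0L) {
            lab[lin] <- nextlab
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  lab
}

# Connected region (4-connectivity) of `mask` containing linear index
# `seed`; logical matrix.
grow_region <- function(mask, seed) {
  lab <- label_components(mask)
  if (!mask[seed]) return(matrix(FALSE, nrow(mask), ncol(mask)))
  lab == lab[seed]
}
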