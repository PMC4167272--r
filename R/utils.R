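# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Angle in degrees of (x, y) about (cx, cy), counter-clockwise from +x,
# wrapped to [0, 360).
angle_deg <- function(x, y, cx = 0, cy = 0) {
  a <- atan2(y - cy, x - cx) * 180 / pi
  (a %% 360)
}

# Wrap an angle difference into [0, 360).
wrap360 <- function(a) ((a %% 360) + 360) %% 360

# TRUE where angle `a` lies in the sector [from, from + width) (degrees,
# measured the same way round as `a`); handles wrap-around.
in_sector <- function(a, from, width) {
  stopifnot(width > 0, width <= 360)
  wrap360(a - from) < width
}

stop_dwcmr <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
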