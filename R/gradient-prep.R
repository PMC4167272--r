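#' Gradient waveform for diffusion preparation
#'
#' A diffusion-preparation gradient axis is described as an ordered list of
#' trapezoidal lobes, each with a signed amplitude (mT/m), ramp-up, flat-top
#' and ramp-down durations (ms), and an optional delay before the lobe.
#' Refocusing-pulse time markers invert the *effective* gradient polarity for
#' everything played after them; all moment and b-value computations operate
#' on the effective waveform.
#'
#' @param lobes data frame (or list coercible to one) with columns
#'   `amplitude`, `ramp_up`, `flat`, `ramp_down`, and optionally `delay`
#'   (defaults to 0).
#' @param refocus_times numeric vector of refocusing markers (ms from the
#'   waveform start).
#' @return An object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(lobes, refocus_times = numeric(0)) {
  lobes <- as.data.frame(lobes)
  if (is.null(lobes$delay)) lobes$delay <- 0
  needed <- c("amplitude", "ramp_up", "flat", "ramp_down", "delay")
  if (!all(needed %in% names(lobes))) {
    stop_dwcmr("lobes need columns amplitude, ramp_up, flat, ramp_down")
  }
  dur <- as.matrix(lobes[c("ramp_up", "flat", "ramp_down", "delay")])
  if (any(dur < 0)) stop_dwcmr("all durations must be non-negative")
  structure(list(lobes = lobes, refocus_times = sort(as.numeric(refocus_times))),
            class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform> %d lobes, %d refocusing marker(s), %.3g ms\n",
              nrow(x$lobes), length(x$refocus_times), waveform_duration(x)))
  print(x$lobes, row.names = FALSE)
  invisible(x)
}

#' Total duration of a waveform (ms)
#' @param wf a [gradient_waveform()].
#' @return Duration in ms.
#' @export
waveform_duration <- function(wf) {
  sum(wf$lobes$delay + wf$lobes$ramp_up + wf$lobes$flat + wf$lobes$ramp_down)
}

# Effective piecewise-linear segments: data frame (t0, t1, g0, g1) with the
# refocusing polarity folded in. Segments of zero length are dropped.
waveform_segments <- function(wf) {
  t <- 0
  seg <- list()
  for (i in seq_len(nrow(wf$lobes))) {
    lb <- wf$lobes[i, ]
    t <- t + lb$delay
    pts <- c(t, t + lb$ramp_up, t + lb$ramp_up + lb$flat,
             t + lb$ramp_up + lb$flat + lb$ramp_down)
    g <- c(0, lb$amplitude, lb$amplitude, 0)
    for (k in 1:3) {
      if (pts[k + 1] > pts[k]) {
        seg[[length(seg) + 1L]] <- c(pts[k], pts[k + 1], g[k], g[k + 1])
      }
    }
    t <- pts[4]
  }
  if (!length(seg)) {
    return(data.frame(t0 = numeric(0), t1 = numeric(0),
                      g0 = numeric(0), g1 = numeric(0)))
  }
  seg <- as.data.frame(do.call(rbind, seg))
  names(seg) <- c("t0", "t1", "g0", "g1")
  # split at refocusing markers, then apply polarity
  for (tr in wf$refocus_times) {
    hit <- which(seg$t0 < tr & seg$t1 > tr)
    for (h in hit) {
      s <- seg[h, ]
      gm <- s$g0 + (s$g1 - s$g0) * (tr - s$t0) / (s$t1 - s$t0)
      seg[h, ] <- c(s$t0, tr, s$g0, gm)
      seg <- rbind(seg, data.frame(t0 = tr, t1 = s$t1, g0 = gm, g1 = s$g1))
    }
  }
  seg <- seg[order(seg$t0), , drop = FALSE]
  if (length(wf$refocus_times)) {
    mid <- (seg$t0 + seg$t1) / 2
    flips <- vapply(mid, function(m) sum(wf$refocus_times <= m), numeric(1))
    pol <- (-1)^flips
    seg$g0 <- seg$g0 * pol
    seg$g1 <- seg$g1 * pol
  }
  seg
}

#' Gradient moments of the effective waveform
#'
#' Closed-form moment `M_n = integral of G_eff(t) t^n dt` over the
#' piecewise-linear effective waveform (exact per trapezoid segment, no
#' quadrature error beyond float rounding). Units: mT.ms^(n+1)/m.
#'
#' @param wf a [gradient_waveform()].
#' @param order moment order, one of 0, 1, 2.
#' @return The moment (numeric scalar).
#' @export
moments <- function(wf, order) {
  if (length(order) != 1L || !(order %in% 0:2)) {
    stop_dwcmr("`order` must be 0, 1, or 2")
  }
  seg <- waveform_segments(wf)
  if (!nrow(seg)) return(0)
  n <- order
  # G(t) = a + b t on [t0, t1]
  b <- (seg$g1 - seg$g0) / (seg$t1 - seg$t0)
  a <- seg$g0 - b * seg$t0
  sum(a * (seg$t1^(n + 1) - seg$t0^(n + 1)) / (n + 1) +
      b * (seg$t1^(n + 2) - seg$t0^(n + 2)) / (n + 2))
}

#' Diffusion b-value of a waveform
#'
#' Computes `b = gamma^2 * integral of q(t)^2 dt` with
#' `q(t) = integral of G_eff`, by exact piecewise-polynomial integration
#' (q is quadratic on every trapezoid segment, so the integrand is quartic).
#'
#' @param wf a [gradient_waveform()].
#' @param gamma gyromagnetic ratio in rad/s/T (default: proton).
#' @return b-value in s/mm^2.
#' @export
b_value <- function(wf, gamma = 267.52218744e6) {
  seg <- waveform_segments(wf)
  if (!nrow(seg)) return(0)
  q0 <- 0      # rad/m
  b <- 0       # rad^2 s / m^2
  t_prev <- 0
  for (i in seq_len(nrow(seg))) {
    gap <- (seg$t0[i] - t_prev) * 1e-3            # zero-gradient interval
    if (gap > 0) b <- b + q0^2 * gap              # q stays constant there
    t_prev <- seg$t1[i]
    dt <- (seg$t1[i] - seg$t0[i]) * 1e-3          # s
    g0 <- seg$g0[i] * 1e-3                        # T/m
    slope <- (seg$g1[i] - seg$g0[i]) * 1e-3 / dt  # T/m/s
    c0 <- q0
    c1 <- gamma * g0
    c2 <- gamma * slope / 2
    p <- c(c0^2, 2 * c0 * c1, c1^2 + 2 * c0 * c2, 2 * c1 * c2, c2^2)
    b <- b + sum(p * dt^(1:5) / (1:5))
    q0 <- c0 + c1 * dt + c2 * dt^2
  }
  b * 1e-6  # s/m^2 -> s/mm^2
}

# ---- quadra-bipolar designer ----------------------------------------------

# Moment vector (M0, M1, M2) of a unit-amplitude trapezoid lobe starting at
# t_start with ramps r and flat f.
unit_lobe_moments <- function(t_start, r, f) {
  wf <- gradient_waveform(data.frame(amplitude = 1, ramp_up = r, flat = f,
                                     ramp_down = r, delay = t_start))
  vapply(0:2, function(n) moments(wf, n), numeric(1))
}

# Build the 4-lobe waveform for a given flat duration and effective
# amplitude vector (length 4); one refocusing marker sits mid-gap between
# lobes 2 and 3 (played amplitudes of lobes 3-4 are sign-flipped so the
# effective amplitudes come out as requested).
quadra_waveform <- function(eff_amp, flat, ramp, gap) {
  lobe_dur <- 2 * ramp + flat
  delays <- c(0, 0, gap, 0)
  played <- eff_amp * c(1, 1, -1, -1)
  wf <- gradient_waveform(
    data.frame(amplitude = played, ramp_up = ramp, flat = flat,
               ramp_down = ramp, delay = delays),
    refocus_times = 2 * lobe_dur + gap / 2
  )
  wf
}

# Effective-amplitude pattern (unit-normalized) nulling M0, M1, M2 for the
# 4-lobe layout at a given flat duration: the 1-D null space of the 3 x 4
# linear moment map.
quadra_null_pattern <- function(flat, ramp, gap) {
  lobe_dur <- 2 * ramp + flat
  starts <- c(0, lobe_dur, 2 * lobe_dur + gap, 3 * lobe_dur + gap)
  M <- vapply(starts, function(ts) unit_lobe_moments(ts, ramp, flat),
              numeric(3))
  v <- svd(M, nu = 0, nv = 4)$v[, 4]
  v / max(abs(v))
}

#' Design a moment-nulled quadra-bipolar diffusion preparation
#'
#' Designs the four-lobe bipolar (quadra-bipolar) gradient waveform of an
#' M1M2-nulled diffusion preparation: zeroth, first and second gradient
#' moments are nulled by construction (the four lobe amplitudes span the
#' null space of the linear moment map for the fixed symmetric timing), the
#' peak amplitude is bounded by the hardware maximum, and the flat-top
#' duration is found by a one-dimensional search so the b-value hits the
#' target. A single refocusing marker sits in the inter-pair gap.
#'
#' @param b_target target b-value (s/mm^2).
#' @param g_max maximum gradient amplitude (mT/m).
#' @param te_prep available preparation window (ms); the waveform (including
#'   the refocusing gap) must fit inside it.
#' @param ramp fixed ramp time per lobe edge (ms).
#' @param refocus_gap time reserved for the refocusing pulse between the two
#'   bipolar pairs (ms).
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @return A [gradient_waveform()] with attributes `b` (achieved b-value) and
#'   `moments` (the three residual moments).
#' @export
design_quadra_bipolar <- function(b_target, g_max, te_prep, ramp = 1,
                                  refocus_gap = 10, gamma = 267.52218744e6) {
  if (b_target < 0 || g_max <= 0 || te_prep <= 0 || ramp <= 0) {
    stop_dwcmr("b_target must be >= 0 and g_max, te_prep, ramp positive")
  }
  flat_max <- (te_prep - refocus_gap - 8 * ramp) / 4
  if (flat_max <= 0) {
    stop_dwcmr(sprintf(
      "infeasible: te_prep = %g ms cannot hold four ramped lobes plus the %g ms refocusing gap (maximal achievable b = 0 s/mm^2)",
      te_prep, refocus_gap))
  }
  build <- function(flat, scale = 1) {
    amp <- quadra_null_pattern(flat, ramp, refocus_gap) * g_max * scale
    quadra_waveform(amp, flat, ramp, refocus_gap)
  }
  if (b_target == 0) {
    wf <- quadra_waveform(rep(0, 4), flat = flat_max, ramp = ramp,
                          gap = refocus_gap)
    attr(wf, "b") <- 0
    attr(wf, "moments") <- c(0, 0, 0)
    return(wf)
  }
  b_at <- function(flat) b_value(build(flat), gamma)
  b_max <- b_at(flat_max)
  if (b_max < b_target) {
    stop_dwcmr(sprintf(
      "infeasible: b = %g s/mm^2 unreachable within te_prep = %g ms at g_max = %g mT/m (maximal achievable b = %.4g s/mm^2)",
      b_target, te_prep, g_max, b_max))
  }
  flat_min <- min(0.05, flat_max / 100)
  b_min <- b_at(flat_min)
  if (b_min >= b_target) {
    # already above target at the shortest sensible lobes: trim amplitude
    wf <- build(flat_min, scale = sqrt(b_target / b_min))
  } else {
    root <- stats::uniroot(function(f) b_at(f) - b_target,
                           lower = flat_min, upper = flat_max,
                           tol = 1e-10)
    wf <- build(root$root)
  }
  attr(wf, "b") <- b_value(wf, gamma)
  attr(wf, "moments") <- vapply(0:2, function(n) moments(wf, n), numeric(1))
  wf
}

#' Serialize a waveform to JSON
#'
#' @param wf a [gradient_waveform()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path) {
  jsonlite::write_json(
    list(lobes = wf$lobes, refocus_times = wf$refocus_times,
         b = attr(wf, "b"), moments = attr(wf, "moments")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
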