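# Shared fixtures: a reduced phantom (smaller FOV, fewer cine phases) keeps
# unit tests fast; geometry and contrast levels match the full defaults.

small_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(fov = 120.4, n_phases = 12, store_cine_images = FALSE,
         snr = Inf, snr_lge = Inf, snr_cine = Inf),
    list(...))
  do.call(phantom_config, args)
}

dice <- function(a, b) {
  a <- if (inherits(a, "infarct_mask")) a$mask$data != 0 else a != 0
  b <- if (inherits(b, "infarct_mask")) b$mask$data != 0 else b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Remote-baseline-subtracted copy of a map (what the pipeline feeds the
# classifiers).
elevation_map <- function(map, roi) {
  out <- map
  out$data <- map$data - mean(map$data[roi], na.rm = TRUE)
  out
}

# Independent dense-quadrature oracle for gradient moments: per effective
# segment the integrand t^n * G(t) is a polynomial of degree <= n + 1 <= 3,
# so composite Simpson over subdivided segments integrates it exactly.
quadrature_moment <- function(wf, order, subdiv = 64) {
  seg <- dwcmr:::waveform_segments(wf)
  total <- 0
  for (i in seq_len(nrow(seg))) {
    tt <- seq(seg$t0[i], seg$t1[i], length.out = 2 * subdiv + 1)
    g <- seg$g0[i] + (seg$g1[i] - seg$g0[i]) *
      (tt - seg$t0[i]) / (seg$t1[i] - seg$t0[i])
    f <- g * tt^order
    h <- tt[2] - tt[1]
    w <- rep(c(4, 2), subdiv)[seq_len(2 * subdiv - 1)]
    total <- total + h / 3 * (f[1] + sum(w * f[2:(2 * subdiv)]) +
                              f[2 * subdiv + 1])
  }
  total
}

random_waveform <- function() {
  nl <- sample(2:5, 1)
  lob <- data.frame(amplitude = runif(nl, -43, 43),
                    ramp_up = runif(nl, 0.2, 2),
                    flat = runif(nl, 0.5, 12),
                    ramp_down = runif(nl, 0.2, 2),
                    delay = runif(nl, 0, 4))
  ref <- if (runif(1) < 0.5) runif(1, 1, 20) else numeric(0)
  gradient_waveform(lob, refocus_times = ref)
}

# Exact two-sided signed-rank p by full enumeration of all sign assignments.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}
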