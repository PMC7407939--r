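# Shared fixtures: all synthetic, generated in code.

# The worked-example arc used throughout: R*C = 5, unit angular span,
# |Re(fCM)| = 0.5.
example_design <- function(v_app, blockage, fcm_real) {
  dimensionless_design(v_app, 5, blockage, fcm_real)
}

# Random feasible designs drawn under a fixed seed; fcm kept away from 0
# and the voltage kept below the full-focusing threshold so trajectories
# stay inside the channel over a unit span.
random_designs <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    fcm <- sample(c(-1, 1), 1) * runif(1, 0.05, 0.5)
    rc <- runif(1, 1, 15)
    d <- runif(1, 0.005, 0.14)
    v_thresh <- rc / (d^2 * abs(fcm))
    dimensionless_design(v_app = runif(1, 0.1, 0.9) * v_thresh,
                         curvature_ratio = rc, blockage = d, fcm_real = fcm)
  })
}

# Independent point-particle pathline oracle: brute-force numerical
# integration of dr*/dtheta* = -Re(fCM) |V*| d*^2 / (R*C + r* - 0.5),
# written out here so it never shares code with the implementation.
ode_exact_oracle <- function(r_start, theta_span, design) {
  rhs <- function(theta, y, parms) {
    list(-design$fcm_real * abs(design$v_app) * design$blockage^2 /
           (design$curvature_ratio + y[[1]] - 0.5))
  }
  sol <- deSolve::ode(y = c(r = r_start), times = c(0, theta_span),
                      func = rhs, parms = NULL, rtol = 1e-12, atol = 1e-12)
  unname(sol[nrow(sol), 2])
}
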