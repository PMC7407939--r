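# 2-D dimensionless particle tracing on the analytic arc field.
#
# The dimensionless model arc has unit width, unit angular span (1 rad)
# and inner radius R*C - 0.5, so the physical dimensionless radius of a
# point at r* is rho = R*C - 0.5 + r*. For a circular arc the Laplace
# solution is exactly analytic (E* = 1/rho, purely azimuthal), so no
# finite-element field solve is needed.

#' Dimensionless particle velocity field in the arc
#'
#' Particle velocity normalised by the electrokinetic reference scale: the
#' azimuthal component is the electrokinetic drift along the field,
#' \eqn{u_\theta^* = E^*(r^*)}, and the radial component combines DEP drift
#' with wall repulsion,
#' \deqn{u_r^* = \frac{V^*_{App} d^{*2}}{2}\left[
#'   \mathrm{Re}(f_{CM})\frac{dE^{*2}}{dr^*} + \frac{3}{256} d^{*3}
#'   E^{*2}\left(\frac{1}{r^{*4}} - \frac{1}{(1-r^*)^4}\right)\right],}
#' evaluated with the closed-form field \eqn{E^* = 1/(R^*_C - 0.5 + r^*)}.
#' The implied pathline slope \eqn{dr^*/d\theta^* = \rho^2 u_r^*} (with
#' \eqn{\rho = R^*_C - 0.5 + r^*}) reproduces the deflection-rate ODE
#' exactly.
#'
#' @param r_star radial coordinate in \code{(0, 1)}.
#' @param design a \code{\link{dimensionless_design}}.
#' @return Named numeric vector \code{c(radial, azimuthal)}.
#' @export
#' @examples
#' d <- dimensionless_design(1562.5, 5, 0.08, -0.5)
#' velocity_field(0.5, d)
velocity_field <- function(r_star, design) {
  design <- as_design(design)
  if (any(r_star <= 0 | r_star >= 1))
    cidep_stop("wall singularity: `r_star` must lie strictly in (0, 1)",
               "singular_wall")
  rho <- design_c(design) + r_star
  e_star <- 1 / rho
  d <- design$blockage
  radial <- abs(design$v_app) * d^2 / 2 *
    (design$fcm_real * (-2 / rho^3) +
       (3 / 256) * d^3 * e_star^2 * (1 / r_star^4 - 1 / (1 - r_star)^4))
  c(radial = radial, azimuthal = e_star)
}

#' Trace a particle through one arc on the 2-D velocity field
#'
#' Arclength-free integration of the particle position driven by
#' \code{\link{velocity_field}}: the pathline slope is
#' \eqn{dr^*/d\theta^* = \rho\, u_r^* / u_\theta^*}. This is the same
#' dynamics as \code{\link{pathline_full}} but exercised through the 2-D
#' velocity formulation; the two agree to solver accuracy. Terminates
#' early at the equilibrium coordinate like \code{pathline_full}.
#'
#' @inheritParams pathline_full
#' @param theta_span angular span of the arc (default 1).
#' @return A \code{cidep_pathline} (see \code{\link{pathline_full}}).
#' @export
#' @examples
#' d <- dimensionless_design(694.44, 5, 0.12, 0.5)
#' pl <- trace_arc(1 - 0.06, d)
#' tail(pl$r_star, 1) # equilibrium coordinate near 0.098
trace_arc <- function(r_start, design, theta_span = 1, n_samples = 500L,
                      eq_tol = 1e-6, rtol = 1e-9, atol = 1e-10) {
  design <- as_design(design)
  check_number(r_start, "r_start", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(theta_span, "theta_span", lower = 0, strict_lower = TRUE)
  times <- seq(0, theta_span, length.out = max(2L, n_samples))
  events <- list()
  if (design$fcm_real == 0 || design$v_app == 0) {
    path <- data.frame(turn_index = 1L, theta_star = times, r_star = r_start)
    return(new_pathline(path, events, design))
  }
  cc <- design_c(design)
  rhs <- function(theta, y, parms) {
    u <- velocity_field(y[[1]], design)
    rho <- cc + y[[1]]
    list(rho * u[["radial"]] / u[["azimuthal"]])
  }
  r_eq <- eq_coord_impl(design$curvature_ratio, design$blockage,
                        design$fcm_real)$r_eq
  rootfun <- function(theta, y, parms) abs(y[[1]] - r_eq) - eq_tol
  sol <- tryCatch(
    deSolve::ode(y = c(r = r_start), times = times, func = rhs, parms = NULL,
                 method = "lsodar", rtol = rtol, atol = atol,
                 rootfunc = rootfun),
    error = function(e) {
      cidep_stop(sprintf("tracer integration failed: %s",
                         conditionMessage(e)), "integration_failure")
    })
  th <- sol[, 1]
  rr <- sol[, 2]
  if (length(th) < length(times)) {
    theta_ev <- th[length(th)]
    events <- c(events, list(list(type = "equilibrium",
                                  theta_star = theta_ev, r_eq = r_eq)))
    rest <- times[times > theta_ev]
    th <- c(th, rest)
    rr <- c(rr, rep(r_eq, length(rest)))
  }
  new_pathline(data.frame(turn_index = 1L, theta_star = th, r_star = rr),
               events, design)
}

#' Multi-turn arc specification
#'
#' A series of identical arcs. The applied voltage splits across identical
#' turns in equal fractions (50\% per turn for two turns), so each turn
#' sees \code{per_turn_voltage_fraction} of the total voltage strength.
#' Opposing turns flip the curvature direction between consecutive arcs,
#' which mirrors the radial coordinate (\eqn{r^* \to 1 - r^*}) at the
#' junction; unidirectional turns pass it through unchanged.
#'
#' @param n_turns number of identical arcs (>= 1).
#' @param orientation \code{"unidirectional"} or \code{"opposing"}.
#' @param per_turn_voltage_fraction voltage fraction per turn; defaults to
#'   \code{1/n_turns} and must sum to 1.
#' @return An object of class \code{cidep_turns}.
#' @export
turn_spec <- function(n_turns = 2L,
                      orientation = c("unidirectional", "opposing"),
                      per_turn_voltage_fraction = NULL) {
  orientation <- match.arg(orientation)
  if (!is.numeric(n_turns) || length(n_turns) != 1L || n_turns < 1 ||
      n_turns != round(n_turns))
    cidep_stop("`n_turns` must be a positive integer", "invalid_input")
  n_turns <- as.integer(n_turns)
  if (is.null(per_turn_voltage_fraction))
    per_turn_voltage_fraction <- rep(1 / n_turns, n_turns)
  if (length(per_turn_voltage_fraction) != n_turns ||
      abs(sum(per_turn_voltage_fraction) - 1) > 1e-12)
    cidep_stop("`per_turn_voltage_fraction` must have one entry per turn and sum to 1",
               "invalid_input")
  structure(list(n_turns = n_turns, orientation = orientation,
                 per_turn_voltage_fraction = per_turn_voltage_fraction),
            class = "cidep_turns")
}

# Closed-form sampled pathline for one turn of the exact model, holding at
# the wall after capture.
exact_turn_samples <- function(r_start, design, times) {
  cc <- design_c(design)
  rhs <- (r_start + cc)^2 -
    2 * design$blockage^2 * design$fcm_real * abs(design$v_app) * times
  r <- sqrt(pmin(pmax(rhs, cc^2), (1 + cc)^2)) - cc
  capture <- rhs < cc^2 | rhs > (1 + cc)^2
  list(r = r, captured = any(capture),
       theta_capture = if (any(capture)) times[which(capture)[1]] else NA)
}

#' Trace a particle through a multi-turn channel
#'
#' Composes single-arc solutions across \code{n_turns} identical arcs. The
#' total voltage strength of \code{design} is split across the turns
#' according to \code{turns$per_turn_voltage_fraction}; each turn is solved
#' independently (closed form for \code{model = "exact"}, full
#' wall-repulsion dynamics for \code{model = "full"}). Between turns an
#' opposing orientation applies the mirror map \eqn{r^* \to 1 - r^*};
#' unidirectional turns pass the exit radius straight through.
#'
#' @param r_start start radius in the first turn.
#' @param design a \code{\link{dimensionless_design}} whose \code{v_app} is
#'   the TOTAL applied voltage strength across all turns.
#' @param turns a \code{\link{turn_spec}}.
#' @param model \code{"exact"} or \code{"full"}.
#' @param n_samples samples per turn.
#' @return A \code{cidep_pathline} whose \code{theta_star} runs from 0 to
#'   \code{n_turns} (unit span per turn), with attribute
#'   \code{exit_positions}: the radius at the end of each turn.
#' @export
#' @examples
#' d <- dimensionless_design(25000, 5, 0.02, -0.5)
#' pl <- trace_multiturn(0, d, turn_spec(2, "opposing"))
#' attr(pl, "exit_positions") # 0.5249, 0.9545
trace_multiturn <- function(r_start, design, turns = turn_spec(),
                            model = c("exact", "full"), n_samples = 500L) {
  design <- as_design(design)
  model <- match.arg(model)
  if (!inherits(turns, "cidep_turns"))
    cidep_stop("`turns` must be a turn_spec()", "invalid_input")
  paths <- list()
  events <- list()
  exits <- numeric(turns$n_turns)
  r_in <- r_start
  for (k in seq_len(turns$n_turns)) {
    v_turn <- design$v_app * turns$per_turn_voltage_fraction[[k]]
    dk <- dimensionless_design(v_turn, design$curvature_ratio,
                               design$blockage, design$fcm_real)
    if (k > 1L && turns$orientation == "opposing")
      r_in <- 1 - r_in
    times <- seq(0, 1, length.out = max(2L, n_samples))
    if (model == "exact") {
      check_number(r_in, sprintf("r_start (turn %d)", k), lower = 0,
                   upper = 1)
      sm <- exact_turn_samples(r_in, dk, times)
      rr <- sm$r
      if (sm$captured)
        events <- c(events, list(list(type = "wall_capture",
                                      theta_star = (k - 1) + sm$theta_capture,
                                      turn_index = k)))
    } else {
      pl <- pathline_full(r_in, 1, dk, n_samples = n_samples)
      rr <- pl$r_star
      times <- pl$theta_star
      for (e in attr(pl, "events")) {
        e$theta_star <- (k - 1) + e$theta_star
        e$turn_index <- k
        events <- c(events, list(e))
      }
    }
    paths[[k]] <- data.frame(turn_index = k, theta_star = (k - 1) + times,
                             r_star = rr)
    r_in <- rr[length(rr)]
    exits[k] <- r_in
  }
  out <- new_pathline(do.call(rbind, paths), events, design)
  attr(out, "exit_positions") <- exits
  attr(out, "turns") <- turns
  out
}
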