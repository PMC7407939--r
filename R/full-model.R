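# Wall-repulsion-corrected ("full") particle dynamics.
#
# The deflection ODE combines the DEP drift with the first-order
# image-force wall repulsion, which scales as (d*)^3 / distance^4 and
# diverges at both walls:
#   dr*/dtheta* = V*App d*^2 [ -Re(fCM)/(R*C + r* - 0.5)
#                              + (3/512) d*^3 (1/r*^4 - 1/(1-r*)^4) ]

# Raw force balance of the full model; vectorised in r.
full_balance <- function(r, curvature_ratio, blockage, fcm_real) {
  -fcm_real / (curvature_ratio + r - 0.5) +
    (3 / 512) * blockage^3 * (1 / r^4 - 1 / (1 - r)^4)
}

#' Radial deflection rate of the full model
#'
#' Right-hand side of the wall-repulsion-corrected pathline ODE,
#' \deqn{\frac{dr^*}{d\theta^*} = V^*_{App} d^{*2}\left[
#'   \frac{-\mathrm{Re}(f_{CM})}{R^*_C + r^* - 0.5} +
#'   \frac{3}{512} d^{*3}\left(\frac{1}{r^{*4}} -
#'   \frac{1}{(1-r^*)^4}\right)\right],}
#' evaluated with \eqn{|V^*_{App}|} (the angular coordinate is measured
#' along the motion). The repulsion term diverges at the walls, so
#' \code{r_star} must lie strictly inside \code{(0, 1)}.
#'
#' @param r_star dimensionless radial coordinate(s) in \code{(0, 1)};
#'   vectorised.
#' @param design a \code{\link{dimensionless_design}}.
#' @param wall_repulsion set \code{FALSE} to suppress the wall term, which
#'   reduces the rate to the point-particle model (useful for model
#'   comparisons).
#' @return \eqn{dr^*/d\theta^*}, same length as \code{r_star}.
#' @export
#' @examples
#' d <- dimensionless_design(3569.5, 5, 0.08, -0.5)
#' deflection_rate(0.5, d) # 2.28448: wall terms cancel at the midpoint
deflection_rate <- function(r_star, design, wall_repulsion = TRUE) {
  design <- as_design(design)
  if (any(r_star <= 0 | r_star >= 1))
    cidep_stop("wall singularity: `r_star` must lie strictly in (0, 1)",
               "singular_wall")
  bal <- if (wall_repulsion) {
    full_balance(r_star, design$curvature_ratio, design$blockage,
                 design$fcm_real)
  } else {
    -design$fcm_real / (design$curvature_ratio + r_star - 0.5)
  }
  abs(design$v_app) * design$blockage^2 * bal
}

# Root of the force balance; internal core shared by the public wrapper and
# by focusing_voltage/run_sweep, which have no voltage yet.
#
# Strategy: sign-change scan on a mesh log-concentrated near both walls
# (the repulsion varies as distance^-4), then Brent refinement. If several
# crossings exist, take the one nearest the destination wall (outer for
# nDEP, inner for pDEP).
eq_coord_impl <- function(curvature_ratio, blockage, fcm_real) {
  if (fcm_real == 0)
    cidep_stop("no DEP: Re(fCM) = 0, equilibrium undefined", "no_dep")
  f <- function(r) full_balance(r, curvature_ratio, blockage, fcm_real)
  edge <- 10^seq(-9, log10(0.5), length.out = 120L)
  mesh <- sort(unique(c(edge, 1 - edge)))
  fv <- f(mesh)
  sc <- which(fv[-1] * fv[-length(fv)] < 0)
  if (length(sc) == 0L)
    cidep_stop("no sign change of the force balance found in (0, 1)",
               "no_equilibrium")
  roots <- vapply(sc, function(i) {
    uniroot(f, lower = mesh[i], upper = mesh[i + 1L],
            tol = .Machine$double.eps^0.9)$root
  }, numeric(1))
  r_eq <- if (fcm_real < 0) max(roots) else min(roots)
  list(r_eq = r_eq, residual = f(r_eq))
}

#' Equilibrium radial coordinate
#'
#' Radial position \eqn{r^*_{Eq}} at which the DEP force is balanced by the
#' wall repulsion, i.e. the root of the deflection-rate bracket. A particle
#' is fully focused at this coordinate, not at the wall itself: for nDEP
#' the root sits near the outer wall, for pDEP near the inner wall.
#'
#' @param design a \code{\link{dimensionless_design}} with
#'   \code{fcm_real != 0} (the equilibrium is voltage-independent).
#' @return An object of class \code{cidep_equilibrium}: list with
#'   \code{r_eq} and the force-balance \code{residual} at the root
#'   (\code{<= 1e-10} in magnitude).
#' @export
#' @examples
#' d <- dimensionless_design(1562.5, 5, 0.08, -0.5)
#' equilibrium_coordinate(d)$r_eq # 0.9245
equilibrium_coordinate <- function(design) {
  design <- as_design(design)
  res <- eq_coord_impl(design$curvature_ratio, design$blockage,
                       design$fcm_real)
  structure(res, class = "cidep_equilibrium")
}

#' @export
print.cidep_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> r*Eq = %.8g (residual %.3g)\n",
              x$r_eq, x$residual))
  invisible(x)
}

#' Focusing voltage of the full model
#'
#' The voltage strength required to fully focus a finite-size particle over
#' a unit angular span, obtained by quadrature of the separated pathline
#' ODE:
#' \deqn{|V^*_{App}| = \left|\frac{1}{d^{*2}} \int
#'   \frac{dr^*}{\mathrm{balance}(r^*)}\right|,}
#' integrated from the realistic start coordinate (\eqn{d^*/2} for nDEP,
#' \eqn{1 - d^*/2} for pDEP) to a point offset slightly inside the
#' equilibrium coordinate. The balance vanishes at \eqn{r^*_{Eq}}, where the
#' integrand diverges logarithmically (the particle approaches equilibrium
#' asymptotically), so the integration limit is \eqn{(1 -
#' \mathrm{offset})\, r^*_{Eq}} for nDEP and \eqn{(1 +
#' \mathrm{offset})\, r^*_{Eq}} for pDEP, with a default offset of 1\%.
#'
#' @param curvature_ratio curvature ratio \eqn{R^*_C > 0.5}.
#' @param blockage blockage ratio \eqn{0 < d^* < 1}.
#' @param fcm_real real part of the Clausius-Mossotti factor (nonzero;
#'   its sign selects the nDEP/pDEP branch).
#' @param eq_offset fractional offset of the integration limit from
#'   \eqn{r^*_{Eq}} (default 0.01).
#' @param rel_tol relative tolerance of the adaptive quadrature.
#' @return An object of class \code{cidep_voltage}: list with
#'   \code{v_app_abs}, the collapsed design quantity
#'   \code{quantity = v_app_abs * |fcm| / R*C}, \code{r_eq} and the
#'   integration limits used.
#' @export
#' @examples
#' focusing_voltage(5, 0.08, 0.5)$v_app_abs # about 1413
focusing_voltage <- function(curvature_ratio, blockage, fcm_real,
                             eq_offset = 0.01, rel_tol = 1e-9) {
  check_number(curvature_ratio, "curvature_ratio", lower = 0.5,
               strict_lower = TRUE)
  check_number(blockage, "blockage", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(fcm_real, "fcm_real", lower = -0.5, upper = 1)
  if (fcm_real == 0)
    cidep_stop("no DEP: Re(fCM) = 0", "no_dep")
  check_number(eq_offset, "eq_offset", lower = 0, upper = 0.5,
               strict_lower = TRUE)
  r_eq <- eq_coord_impl(curvature_ratio, blockage, fcm_real)$r_eq
  if (fcm_real < 0) {
    lower <- blockage / 2
    upper <- (1 - eq_offset) * r_eq
  } else {
    lower <- (1 + eq_offset) * r_eq
    upper <- 1 - blockage / 2
  }
  if (upper <= lower)
    cidep_stop(paste0("infeasible focusing: the equilibrium offset band ",
                      "overlaps the particle start position (d* too large ",
                      "for this geometry)"),
               "infeasible_focusing")
  ig <- integrate(function(r) 1 / full_balance(r, curvature_ratio, blockage,
                                               fcm_real),
                  lower = lower, upper = upper,
                  rel.tol = rel_tol, subdivisions = 500L)
  v <- abs(ig$value) / blockage^2
  structure(list(v_app_abs = v,
                 quantity = v * abs(fcm_real) / curvature_ratio,
                 r_eq = r_eq, lower = lower, upper = upper,
                 eq_offset = eq_offset, abs_error = ig$abs.error / blockage^2),
            class = "cidep_voltage")
}

#' @export
print.cidep_voltage <- function(x, ...) {
  cat(sprintf(paste0("<focusing voltage> |V*App| = %.8g ",
                     "(quantity |V*||fCM|/R*C = %.8g, r*Eq = %.6g)\n"),
              x$v_app_abs, x$quantity, x$r_eq))
  invisible(x)
}

#' Wall-repulsion-corrected pathline
#'
#' Integrates the full deflection ODE as an initial-value problem in
#' \eqn{\theta^*} with an adaptive solver. Integration terminates early when
#' the particle reaches the equilibrium coordinate (within \code{eq_tol});
#' beyond that event the particle travels along \eqn{r^*_{Eq}} and the
#' remaining samples hold that value.
#'
#' @param r_start start radius, within \code{[d*/2, 1 - d*/2]}.
#' @param theta_end angular span to integrate over (1 = full arc).
#' @param design a \code{\link{dimensionless_design}}.
#' @param n_samples number of output samples along the span.
#' @param eq_tol radial tolerance of the equilibrium-reached event.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param wall_repulsion set \code{FALSE} to integrate the point-particle
#'   ODE instead (no equilibrium event; for model-reduction checks).
#' @return An object of class \code{cidep_pathline}: a data frame with
#'   columns \code{turn_index}, \code{theta_star}, \code{r_star}, plus
#'   attributes \code{events} (list of annotations with the \eqn{\theta^*}
#'   of occurrence) and \code{design}.
#' @export
#' @examples
#' d <- dimensionless_design(1562.5, 5, 0.08, -0.5)
#' pl <- pathline_full(0.04, 1, d)
#' tail(pl$r_star, 1) # held at the equilibrium coordinate 0.9245
pathline_full <- function(r_start, theta_end, design, n_samples = 500L,
                          eq_tol = 1e-6, rtol = 1e-9, atol = 1e-10,
                          wall_repulsion = TRUE) {
  design <- as_design(design)
  half <- design$blockage / 2
  check_number(r_start, "r_start", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(theta_end, "theta_end", lower = 0, strict_lower = TRUE)
  times <- seq(0, theta_end, length.out = max(2L, n_samples))
  events <- list()

  if (design$fcm_real == 0 || design$v_app == 0) {
    path <- data.frame(turn_index = 1L, theta_star = times, r_star = r_start)
    return(new_pathline(path, events, design))
  }

  rhs <- function(theta, y, parms) {
    list(deflection_rate(y[[1]], design, wall_repulsion = wall_repulsion))
  }
  rootfun <- NULL
  r_eq <- NA_real_
  if (wall_repulsion) {
    r_eq <- eq_coord_impl(design$curvature_ratio, design$blockage,
                          design$fcm_real)$r_eq
    rootfun <- function(theta, y, parms) abs(y[[1]] - r_eq) - eq_tol
  }
  sol <- tryCatch(
    deSolve::ode(y = c(r = r_start), times = times, func = rhs, parms = NULL,
                 method = "lsodar", rtol = rtol, atol = atol,
                 rootfunc = rootfun),
    error = function(e) {
      cidep_stop(sprintf(
        paste0("pathline integration failed (r_start = %g, d* = %g, ",
               "|V*| = %g): %s"),
        r_start, design$blockage, abs(design$v_app), conditionMessage(e)),
        "integration_failure")
    })
  th <- sol[, 1]
  rr <- sol[, 2]
  if (length(th) < length(times)) {
    # equilibrium event fired: hold r* = r*Eq for the rest of the arc
    theta_ev <- th[length(th)]
    events <- c(events, list(list(type = "equilibrium", theta_star = theta_ev,
                                  r_eq = r_eq)))
    rest <- times[times > theta_ev]
    th <- c(th, rest)
    rr <- c(rr, rep(r_eq, length(rest)))
  }
  path <- data.frame(turn_index = 1L, theta_star = th, r_star = rr)
  new_pathline(path, events, design)
}

new_pathline <- function(path, events, design) {
  structure(path, events = events, design = design,
            class = c("cidep_pathline", "data.frame"))
}

#' @export
print.cidep_pathline <- function(x, ...) {
  n <- nrow(x)
  ev <- attr(x, "events")
  cat(sprintf(
    "<pathline> %d samples over %d turn(s), r*: %.6g -> %.6g\n",
    n, max(x$turn_index), x$r_star[1], x$r_star[n]))
  for (e in ev)
    cat(sprintf("  event: %s at theta* = %.6g\n", e$type, e$theta_star))
  invisible(x)
}
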