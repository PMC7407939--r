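#' Closed-form (point-particle) pathline endpoint
#'
#' For an infinitesimally small particle the wall-repulsion term vanishes
#' and the pathline ODE integrates in closed form: with
#' \eqn{C = R^*_C - 0.5},
#' \deqn{(r_2^* + C)^2 = (r_1^* + C)^2 -
#'   2 d^{*2}\, \mathrm{Re}(f_{CM})\, |V^*_{App}|\, \Delta\theta^*,}
#' where \eqn{\Delta\theta^*} is the angular span measured along the
#' direction of the electrokinetic motion. Negative DEP
#' (\eqn{\mathrm{Re}(f_{CM}) < 0}) drives the particle outward, positive DEP
#' inward. If the closed form would carry the particle beyond a wall the
#' result is clamped to the wall coordinate and flagged as a wall capture;
#' \code{fcm_real = 0} returns the start radius unchanged (pure
#' electrokinetic transport).
#'
#' @param r_start dimensionless start radius \eqn{r_1^*} in \code{[0, 1]}.
#' @param theta_span angular span \eqn{\Delta\theta^* \ge 0} traversed along
#'   the motion (1 = the full arc).
#' @param design a \code{\link{dimensionless_design}}.
#' @return A list of class \code{cidep_arc_step} with \code{r_end},
#'   \code{wall_capture} (logical) and \code{wall} (\code{"inner"},
#'   \code{"outer"} or \code{NA}).
#' @export
#' @examples
#' d <- dimensionless_design(3569.5, 5, 0.05, -0.5)
#' pathline_exact(0, 1, d)$r_end # 0.901
pathline_exact <- function(r_start, theta_span, design) {
  design <- as_design(design)
  check_number(r_start, "r_start", lower = 0, upper = 1)
  check_number(theta_span, "theta_span", lower = 0)
  cc <- design_c(design)
  rhs <- (r_start + cc)^2 -
    2 * design$blockage^2 * design$fcm_real * abs(design$v_app) * theta_span
  if (rhs < cc^2) {
    res <- list(r_end = 0, wall_capture = TRUE, wall = "inner")
  } else if (rhs > (1 + cc)^2) {
    res <- list(r_end = 1, wall_capture = TRUE, wall = "outer")
  } else {
    res <- list(r_end = sqrt(rhs) - cc, wall_capture = FALSE, wall = NA)
  }
  structure(res, class = "cidep_arc_step")
}

#' @export
print.cidep_arc_step <- function(x, ...) {
  cat(sprintf("<arc step> r_end = %.6g%s\n", x$r_end,
              if (x$wall_capture) paste0(" (captured at ", x$wall, " wall)")
              else ""))
  invisible(x)
}

#' Full-focusing design identity
#'
#' The point-particle solution collapses the full-focusing condition (wall
#' to wall over a unit angular span) into
#' \deqn{\frac{|V^*_{App}|\, d^{*2}\, |\mathrm{Re}(f_{CM})|}{R^*_C} = 1.}
#' Values below 1 under-focus, values above 1 over-focus.
#'
#' @param design a \code{\link{dimensionless_design}} with
#'   \code{fcm_real != 0}.
#' @return The identity value (dimensionless, 1 at threshold).
#' @export
#' @examples
#' focusing_identity(dimensionless_design(25000, 5, 0.02, -0.5)) # 1
focusing_identity <- function(design) {
  design <- as_design(design)
  if (design$fcm_real == 0)
    cidep_stop("no DEP: Re(fCM) = 0", "no_dep")
  abs(design$v_app) * design$blockage^2 * abs(design$fcm_real) /
    design$curvature_ratio
}

#' Design thresholds for full focusing
#'
#' Rearrangements of the full-focusing identity. Given any two of the
#' curvature ratio, blockage ratio and voltage strength (plus
#' \eqn{|\mathrm{Re}(f_{CM})|}), computes the threshold value of the third:
#' \deqn{|V^*_{App}|_{Min} = \frac{R^*_C}{d^{*2} |f_{CM}|}, \quad
#'       d^*_{Min} = \sqrt{\frac{R^*_C}{|V^*_{App}| |f_{CM}|}}, \quad
#'       R^*_{C,Max} = |V^*_{App}|\, d^{*2}\, |f_{CM}|.}
#' These are, respectively, the minimum voltage that fully focuses a given
#' particle in a given geometry, the smallest particle a given voltage can
#' fully focus, and the largest (gentlest) curvature that still focuses.
#'
#' @param curvature_ratio \eqn{R^*_C}, or \code{NULL} if it is the unknown.
#' @param blockage \eqn{d^*}, or \code{NULL} if it is the unknown.
#' @param v_app \eqn{|V^*_{App}|}, or \code{NULL} if it is the unknown.
#' @param fcm_abs \eqn{|\mathrm{Re}(f_{CM})|} (> 0).
#' @return An object of class \code{cidep_thresholds}: a list with the
#'   supplied values plus the computed member among \code{v_min},
#'   \code{d_min}, \code{r_max}.
#' @export
#' @examples
#' design_thresholds(curvature_ratio = 5, blockage = 0.02,
#'                   fcm_abs = 0.5)$v_min # 25000
design_thresholds <- function(curvature_ratio = NULL, blockage = NULL,
                              v_app = NULL, fcm_abs) {
  check_number(fcm_abs, "fcm_abs", lower = 0, strict_lower = TRUE, upper = 1)
  known <- c(curvature_ratio = !is.null(curvature_ratio),
             blockage = !is.null(blockage),
             v_app = !is.null(v_app))
  if (sum(known) != 2L)
    cidep_stop(paste0("supply exactly two of `curvature_ratio`, `blockage`",
                      ", `v_app`"), "invalid_input")
  for (nm in names(known)[known])
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  out <- list(curvature_ratio = curvature_ratio, blockage = blockage,
              v_app = if (is.null(v_app)) NULL else abs(v_app),
              fcm_abs = fcm_abs)
  if (!known[["v_app"]]) {
    if (blockage <= 0)
      cidep_stop("zero blockage: threshold undefined", "undefined_threshold")
    out$v_min <- curvature_ratio / (blockage^2 * fcm_abs)
  } else if (!known[["blockage"]]) {
    out$d_min <- sqrt(curvature_ratio / (abs(v_app) * fcm_abs))
  } else {
    out$r_max <- abs(v_app) * blockage^2 * fcm_abs
  }
  structure(out, class = "cidep_thresholds")
}

#' @export
print.cidep_thresholds <- function(x, ...) {
  cat("<full-focusing thresholds (point-particle model)>\n")
  lab <- c(curvature_ratio = "R*C", blockage = "d*", v_app = "|V*App|",
           fcm_abs = "|Re(fCM)|", v_min = "|V*App| min", d_min = "d* min",
           r_max = "R*C max")
  for (nm in names(x))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-12s %.8g\n", lab[[nm]], x[[nm]]))
  invisible(x)
}

#' Angular span needed to move between two radii (point-particle model)
#'
#' Algebraic inverse of \code{\link{pathline_exact}}:
#' \deqn{\Delta\theta^* = \frac{(r_1^*+C)^2 - (r_2^*+C)^2}
#'   {2 d^{*2}\, \mathrm{Re}(f_{CM})\, |V^*_{App}|}.}
#' Positive results mean the move is possible in the forward direction of
#' motion for the design's DEP sign.
#'
#' @param r_start,r_end dimensionless radii in \code{[0, 1]}.
#' @param design a \code{\link{dimensionless_design}} with nonzero voltage
#'   and \code{fcm_real}.
#' @return The angular span \eqn{\Delta\theta^*} (dimensionless).
#' @export
#' @examples
#' d <- dimensionless_design(25000, 5, 0.02, -0.5)
#' angle_to_reach(0, 1, d) # 1: full focusing exactly at threshold
angle_to_reach <- function(r_start, r_end, design) {
  design <- as_design(design)
  check_number(r_start, "r_start", lower = 0, upper = 1)
  check_number(r_end, "r_end", lower = 0, upper = 1)
  if (design$fcm_real == 0 || design$v_app == 0)
    cidep_stop("no deflection: Re(fCM) or V*App is zero", "no_deflection")
  cc <- design_c(design)
  ((r_start + cc)^2 - (r_end + cc)^2) /
    (2 * design$blockage^2 * design$fcm_real * abs(design$v_app))
}
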