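#' Dimensionless C-iDEP design
#'
#' The complete dimensionless state of an arc-channel design: the signed
#' applied-voltage strength \eqn{V^*_{App} = V_0(1+\alpha^2)/(6(\zeta_p -
#' \zeta_w))}, the curvature ratio \eqn{R^*_C = R_c/W}, the particle blockage
#' ratio \eqn{d^* = d/W} and the real part of the Clausius-Mossotti factor.
#' \eqn{V^*_{App}} is positive for counter-clockwise electrokinetic motion
#' and negative for clockwise motion; all models internally operate on
#' \eqn{|V^*_{App}|} with the angular coordinate measured along the motion,
#' since the direction only flips the sign of the pathline solution.
#'
#' @param v_app signed dimensionless applied-voltage strength.
#' @param curvature_ratio curvature ratio \eqn{R^*_C > 0.5}.
#' @param blockage particle blockage ratio \eqn{0 < d^* < 1}.
#' @param fcm_real real part of the Clausius-Mossotti factor, in
#'   \code{[-0.5, 1]}; negative for nDEP (deflection towards the outer
#'   wall), positive for pDEP (towards the inner wall).
#' @return An object of class \code{cidep_design} with fields \code{v_app},
#'   \code{curvature_ratio}, \code{blockage}, \code{fcm_real} and the derived
#'   \code{ek_direction} (\code{"ccw"} or \code{"cw"}).
#' @export
#' @examples
#' dimensionless_design(v_app = 25000, curvature_ratio = 5,
#'                      blockage = 0.02, fcm_real = -0.5)
dimensionless_design <- function(v_app, curvature_ratio, blockage, fcm_real) {
  check_number(v_app, "v_app")
  check_number(curvature_ratio, "curvature_ratio", lower = 0.5,
               strict_lower = TRUE)
  check_number(blockage, "blockage", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(fcm_real, "fcm_real", lower = -0.5, upper = 1)
  structure(list(v_app = v_app,
                 curvature_ratio = curvature_ratio,
                 blockage = blockage,
                 fcm_real = fcm_real,
                 ek_direction = if (v_app < 0) "cw" else "ccw"),
            class = "cidep_design")
}

#' @export
print.cidep_design <- function(x, ...) {
  cat(sprintf(paste0("<C-iDEP design> V*App = %g (%s EK motion), ",
                     "R*C = %g, d* = %g, Re(fCM) = %g (%s)\n"),
              x$v_app, x$ek_direction, x$curvature_ratio, x$blockage,
              x$fcm_real,
              if (x$fcm_real < 0) "nDEP" else if (x$fcm_real > 0) "pDEP"
              else "no DEP"))
  invisible(x)
}

as_design <- function(x) {
  if (!inherits(x, "cidep_design"))
    cidep_stop("expected a `cidep_design` object", "invalid_input")
  x
}

# Shifted-radius constant C = R*C - 0.5 so that the physical dimensionless
# radius is C + r*.
design_c <- function(design) design$curvature_ratio - 0.5

dep_sign_of <- function(fcm_real) {
  if (fcm_real < 0) "negative" else if (fcm_real > 0) "positive" else "none"
}

match_dep_sign <- function(dep_sign) {
  dep_sign <- match.arg(dep_sign, c("positive", "negative", "pos", "neg",
                                    "pdep", "ndep"))
  if (dep_sign %in% c("pos", "pdep")) dep_sign <- "positive"
  if (dep_sign %in% c("neg", "ndep")) dep_sign <- "negative"
  dep_sign
}
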