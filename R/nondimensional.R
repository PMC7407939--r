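#' Convert dimensional device parameters to a dimensionless design
#'
#' Maps the dimensional channel/drive/particle description onto the three
#' dimensionless numbers governing arc-channel C-iDEP:
#' \deqn{V^*_{App} = \frac{V_0 (1+\alpha^2)}{6(\zeta_p-\zeta_w)}, \qquad
#'       R^*_C = \frac{R_c}{W}, \qquad d^* = \frac{d}{W}.}
#'
#' @param channel a \code{\link{channel_spec}}.
#' @param drive a \code{\link{drive_spec}}.
#' @param particle a \code{\link{particle_spec}}.
#' @param fcm_real real part of the Clausius-Mossotti factor; compute it
#'   with \code{\link{clausius_mossotti}} or supply it directly.
#' @return A \code{\link{dimensionless_design}}.
#' @export
#' @examples
#' ch <- channel_spec(width = 200e-6, mean_radius = 1e-3)
#' dr <- drive_spec(100)
#' pa <- particle_spec(1e-6, 2.55, 2e-3, zeta = 0.05)
#' nondimensionalize(ch, dr, pa, fcm_real = -0.5)
nondimensionalize <- function(channel, drive, particle, fcm_real) {
  if (!inherits(channel, "cidep_channel"))
    cidep_stop("`channel` must be a channel_spec()", "invalid_input")
  if (!inherits(drive, "cidep_drive"))
    cidep_stop("`drive` must be a drive_spec()", "invalid_input")
  if (!inherits(particle, "cidep_particle"))
    cidep_stop("`particle` must be a particle_spec()", "invalid_input")
  zeta_diff <- particle$zeta - channel$wall_zeta
  if (zeta_diff == 0)
    cidep_stop(paste0("particle and wall zeta potentials are equal: no ",
                      "electrokinetic transport"),
               "zero_ek_velocity")
  if (particle$diameter >= channel$width)
    cidep_stop("particle diameter >= channel width: blockage infeasible",
               "blockage_infeasible")
  v_app <- drive$dc_voltage * (1 + drive$ac_ratio^2) / (6 * zeta_diff)
  dimensionless_design(v_app = v_app,
                       curvature_ratio = channel$mean_radius / channel$width,
                       blockage = particle$diameter / channel$width,
                       fcm_real = fcm_real)
}

#' Dimensional voltage from a dimensionless voltage strength
#'
#' Inverse of the voltage component of \code{\link{nondimensionalize}}:
#' \eqn{V_0 = 6 V^*_{App} (\zeta_p - \zeta_w) / (1+\alpha^2)}.
#'
#' @param v_app dimensionless (signed) applied-voltage strength.
#' @param alpha RMS AC/DC ratio.
#' @param zeta_diff \eqn{\zeta_p - \zeta_w} in V.
#' @return DC voltage \eqn{V_0} in V.
#' @export
#' @examples
#' dimensional_voltage(333.3333, alpha = 0, zeta_diff = 0.05) # 100 V
dimensional_voltage <- function(v_app, alpha = 0, zeta_diff) {
  check_number(v_app, "v_app")
  check_number(alpha, "alpha", lower = 0)
  check_number(zeta_diff, "zeta_diff")
  6 * v_app * zeta_diff / (1 + alpha^2)
}

#' Analytic dimensionless field magnitude in the arc
#'
#' The potential in the arc satisfies the Laplace equation with the voltage
#' drop applied across the angular span, giving a purely azimuthal field
#' whose magnitude falls off as the inverse of the radius. For a unit
#' voltage drop over a unit-radian arc of unit width the dimensionless
#' magnitude is
#' \deqn{E^* (r^*) = \frac{1}{R^*_C - 0.5 + r^*},}
#' strictly decreasing from the inner to the outer wall. This inner/outer
#' field asymmetry is the sole source of the DEP force in C-iDEP devices.
#'
#' @param r_star dimensionless radial coordinate(s) in \code{[0, 1]};
#'   vectorised.
#' @param design a \code{\link{dimensionless_design}} (only
#'   \code{curvature_ratio} is used).
#' @return Dimensionless azimuthal field magnitude \eqn{E^*}, same length as
#'   \code{r_star}.
#' @export
#' @examples
#' d <- dimensionless_design(1, 5, 0.01, -0.5)
#' arc_field_magnitude(0.5, d) # 0.2
arc_field_magnitude <- function(r_star, design) {
  design <- as_design(design)
  if (any(r_star < 0 | r_star > 1))
    cidep_stop("`r_star` must lie in [0, 1]", "invalid_input")
  1 / (design_c(design) + r_star)
}
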