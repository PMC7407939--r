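#' Suspending-fluid specification
#'
#' Describes the electrical and viscous properties of the suspending liquid.
#' Permittivity is supplied relative to vacuum and multiplied by
#' \eqn{\varepsilon_0 = 8.8541878128 \times 10^{-12}} F/m internally.
#'
#' @param rel_permittivity relative permittivity \eqn{\varepsilon_f/\varepsilon_0}
#'   (dimensionless, e.g. 78 for aqueous buffers).
#' @param conductivity electrical conductivity \eqn{\sigma_f} in S/m
#'   (zero models an ideal dielectric liquid).
#' @param viscosity dynamic viscosity \eqn{\eta_f} in Pa s. Carried for
#'   completeness; the dimensionless particle dynamics are independent of it.
#' @return An object of class \code{cidep_fluid}.
#' @export
#' @examples
#' fluid_spec(78, 1e-2)
fluid_spec <- function(rel_permittivity, conductivity, viscosity = 1e-3) {
  check_number(rel_permittivity, "rel_permittivity", lower = 0,
               strict_lower = TRUE)
  check_number(conductivity, "conductivity", lower = 0)
  check_number(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  structure(list(rel_permittivity = rel_permittivity,
                 conductivity = conductivity,
                 viscosity = viscosity),
            class = "cidep_fluid")
}

#' Particle specification
#'
#' @param diameter particle diameter \eqn{d} in m.
#' @param rel_permittivity relative permittivity
#'   \eqn{\varepsilon_p/\varepsilon_0} (dimensionless).
#' @param conductivity electrical conductivity \eqn{\sigma_p} in S/m.
#' @param zeta particle zeta potential \eqn{\zeta_p} in V.
#' @return An object of class \code{cidep_particle}.
#' @export
#' @examples
#' particle_spec(1e-6, 2.55, 2e-3, zeta = -0.04)
particle_spec <- function(diameter, rel_permittivity, conductivity,
                          zeta = 0) {
  check_number(diameter, "diameter", lower = 0, strict_lower = TRUE)
  check_number(rel_permittivity, "rel_permittivity", lower = 0)
  check_number(conductivity, "conductivity", lower = 0)
  check_number(zeta, "zeta")
  structure(list(diameter = diameter,
                 rel_permittivity = rel_permittivity,
                 conductivity = conductivity,
                 zeta = zeta),
            class = "cidep_particle")
}

#' Circular-arc channel specification
#'
#' A channel of uniform width \code{W} and mean curvature radius \code{Rc}
#' subtending an angle \code{beta} at the centre of curvature. The inner and
#' outer wall radii are derived as \eqn{R_i = R_c - W/2} and
#' \eqn{R_o = R_c + W/2}. Height is bookkeeping only: the field has no
#' depth-wise component, so the physics reduce to the r-theta plane.
#'
#' @param width channel width \eqn{W} in m.
#' @param mean_radius mean radius of curvature \eqn{R_c} in m; must exceed
#'   \code{width/2} so the inner radius is positive.
#' @param angle subtended angle \eqn{\beta} in rad.
#' @param height channel height \eqn{H} in m (carried, never used).
#' @param wall_zeta wall zeta potential \eqn{\zeta_w} in V.
#' @return An object of class \code{cidep_channel} with derived
#'   \code{inner_radius} and \code{outer_radius}.
#' @export
#' @examples
#' channel_spec(width = 200e-6, mean_radius = 1e-3, angle = 1)
channel_spec <- function(width, mean_radius, angle = 1, height = 50e-6,
                         wall_zeta = 0) {
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  check_number(mean_radius, "mean_radius", lower = width / 2,
               strict_lower = TRUE)
  check_number(angle, "angle", lower = 0, strict_lower = TRUE)
  check_number(height, "height", lower = 0, strict_lower = TRUE)
  check_number(wall_zeta, "wall_zeta")
  structure(list(width = width, mean_radius = mean_radius, angle = angle,
                 height = height, wall_zeta = wall_zeta,
                 inner_radius = mean_radius - width / 2,
                 outer_radius = mean_radius + width / 2),
            class = "cidep_channel")
}

#' Drive (applied voltage) specification
#'
#' A DC voltage drop optionally biased with an AC component characterised by
#' its RMS AC-to-DC ratio. The AC part does not contribute to electrokinetic
#' transport (its time average vanishes) but enters all field-squared
#' quantities through the factor \eqn{(1+\alpha^2)}.
#'
#' @param dc_voltage DC voltage drop \eqn{V_0} in V.
#' @param ac_ratio RMS AC/DC ratio \eqn{\alpha} (dimensionless, >= 0).
#' @param frequency AC frequency in Hz; 0 means pure DC and the
#'   Clausius-Mossotti factor is evaluated in its conductivity-only limit.
#' @return An object of class \code{cidep_drive}.
#' @export
#' @examples
#' drive_spec(100, ac_ratio = 1, frequency = 1e3)
drive_spec <- function(dc_voltage, ac_ratio = 0, frequency = 0) {
  check_number(dc_voltage, "dc_voltage")
  check_number(ac_ratio, "ac_ratio", lower = 0)
  check_number(frequency, "frequency", lower = 0)
  structure(list(dc_voltage = dc_voltage, ac_ratio = ac_ratio,
                 frequency = frequency),
            class = "cidep_drive")
}

#' Position inside the dimensionless arc
#'
#' Radial coordinate \eqn{r^* = (r - R_i)/W} (0 = inner wall, 1 = outer
#' wall) and angular coordinate \eqn{\theta^* = \theta/\beta}, both in
#' \code{[0, 1]}. A finite particle centre is confined to
#' \code{[d*/2, 1 - d*/2]}.
#'
#' @param r_star dimensionless radial coordinate in \code{[0, 1]}.
#' @param theta_star dimensionless angular coordinate in \code{[0, 1]}.
#' @return An object of class \code{cidep_position}.
#' @export
arc_position <- function(r_star, theta_star = 0) {
  check_number(r_star, "r_star", lower = 0, upper = 1)
  check_number(theta_star, "theta_star", lower = 0, upper = 1)
  structure(list(r_star = r_star, theta_star = theta_star),
            class = "cidep_position")
}

#' @export
print.cidep_fluid <- function(x, ...) {
  cat(sprintf("<fluid> eps_f/eps0 = %g, sigma_f = %g S/m, eta_f = %g Pa s\n",
              x$rel_permittivity, x$conductivity, x$viscosity))
  invisible(x)
}

#' @export
print.cidep_particle <- function(x, ...) {
  cat(sprintf(
    "<particle> d = %g m, eps_p/eps0 = %g, sigma_p = %g S/m, zeta_p = %g V\n",
    x$diameter, x$rel_permittivity, x$conductivity, x$zeta))
  invisible(x)
}

#' @export
print.cidep_channel <- function(x, ...) {
  cat(sprintf(
    "<channel> W = %g m, Rc = %g m (Ri = %g, Ro = %g), beta = %g rad\n",
    x$width, x$mean_radius, x$inner_radius, x$outer_radius, x$angle))
  invisible(x)
}

#' @export
print.cidep_drive <- function(x, ...) {
  cat(sprintf("<drive> V0 = %g V, alpha = %g, f = %g Hz\n",
              x$dc_voltage, x$ac_ratio, x$frequency))
  invisible(x)
}
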