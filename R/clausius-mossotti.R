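#' Clausius-Mossotti factor of a particle-fluid system
#'
#' Complex polarisability contrast between a spherical particle and the
#' suspending fluid,
#' \deqn{f_{CM} = \frac{(\varepsilon_p-\varepsilon_f) +
#'   j(\sigma_p-\sigma_f)/(2\pi f)}{(\varepsilon_p+2\varepsilon_f) +
#'   j(\sigma_p+2\sigma_f)/(2\pi f)},}
#' with absolute permittivities \eqn{\varepsilon_x = \varepsilon_0 \cdot}
#' relative permittivity. The real part lies in \code{[-0.5, 1]} and sets the
#' sign and strength of dielectrophoresis: negative values (nDEP) push the
#' particle away from high field, positive values (pDEP) towards it.
#'
#' At \code{frequency = 0} (pure DC) the formula is evaluated in its
#' conductivity-only limit \eqn{(\sigma_p-\sigma_f)/(\sigma_p+2\sigma_f)},
#' the formal \eqn{f \to 0} limit of the expression above.
#'
#' @param particle a \code{\link{particle_spec}}.
#' @param fluid a \code{\link{fluid_spec}}.
#' @param frequency drive frequency in Hz; 0 selects the DC limit.
#' @return A single complex number \eqn{f_{CM}}.
#' @export
#' @examples
#' p <- particle_spec(1e-6, 2.55, 2e-3)
#' f <- fluid_spec(78, 1e-2)
#' Re(clausius_mossotti(p, f, frequency = 1e3))
clausius_mossotti <- function(particle, fluid, frequency) {
  if (!inherits(particle, "cidep_particle"))
    cidep_stop("`particle` must be a particle_spec()", "invalid_input")
  if (!inherits(fluid, "cidep_fluid"))
    cidep_stop("`fluid` must be a fluid_spec()", "invalid_input")
  check_number(frequency, "frequency", lower = 0)
  sp <- particle$conductivity
  sf <- fluid$conductivity
  if (frequency == 0) {
    if (sp + 2 * sf == 0)
      cidep_stop(paste0("Clausius-Mossotti factor is undefined at DC when ",
                        "both conductivities are zero"),
                 "undefined_factor")
    return(complex(real = (sp - sf) / (sp + 2 * sf), imaginary = 0))
  }
  ep <- particle$rel_permittivity * .eps0
  ef <- fluid$rel_permittivity * .eps0
  w <- 2 * pi * frequency
  num <- complex(real = ep - ef, imaginary = (sp - sf) / w)
  den <- complex(real = ep + 2 * ef, imaginary = (sp + 2 * sf) / w)
  if (Mod(den) == 0)
    cidep_stop("Clausius-Mossotti denominator vanishes", "undefined_factor")
  num / den
}
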