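# Canonical parameter sweep over the practically relevant design space.

default_blockages <- function() {
  c(seq(0.001, 0.01, by = 0.001),
    c(0.0125, 0.015, 0.0175, 0.02),
    seq(0.03, 0.15, by = 0.01))
}

#' Construct a parameter-sweep grid
#'
#' @param dep_sign \code{"positive"} or \code{"negative"} DEP (abbreviations
#'   \code{"pos"}/\code{"neg"} accepted).
#' @param curvature_ratios values of \eqn{R^*_C}.
#' @param blockages strictly increasing values of \eqn{d^*}.
#' @param fcm_values values of \eqn{\mathrm{Re}(f_{CM})}; must match
#'   \code{dep_sign}.
#' @return An object of class \code{cidep_sweep_grid}.
#' @export
sweep_grid <- function(dep_sign, curvature_ratios, blockages, fcm_values) {
  dep_sign <- match_dep_sign(dep_sign)
  if (any(diff(blockages) <= 0))
    cidep_stop("`blockages` must be strictly increasing with no duplicates",
               "invalid_input")
  ok <- if (dep_sign == "negative") all(fcm_values < 0) else
    all(fcm_values > 0)
  if (!ok)
    cidep_stop("`fcm_values` signs do not match `dep_sign`", "invalid_input")
  structure(list(dep_sign = dep_sign,
                 curvature_ratios = curvature_ratios,
                 blockages = blockages,
                 fcm_values = fcm_values),
            class = "cidep_sweep_grid")
}

#' Canonical sweep grid
#'
#' The reference design-space grid: 15 curvature ratios (\eqn{R^*_C} = 1 to
#' 15 in steps of 1), 27 blockage ratios (\eqn{d^*} from 0.001 to 0.01 in
#' steps of 0.001, 0.01 to 0.02 in steps of 0.0025, and 0.02 to 0.15 in
#' steps of 0.01) and 10 Clausius-Mossotti values per DEP sign
#' (\eqn{-0.05} to \eqn{-0.5} in steps of \eqn{-0.05} for nDEP, 0.1 to 1 in
#' steps of 0.1 for pDEP): 4050 combinations per sign, spanning published
#' curvature radii and particle/cell sizes.
#'
#' @inheritParams sweep_grid
#' @return An object of class \code{cidep_sweep_grid}.
#' @export
#' @examples
#' g <- default_grid("negative")
#' length(g$curvature_ratios) * length(g$blockages) * length(g$fcm_values)
default_grid <- function(dep_sign) {
  dep_sign <- match_dep_sign(dep_sign)
  fcm <- if (dep_sign == "negative") seq(-0.05, -0.5, by = -0.05) else
    seq(0.1, 1, by = 0.1)
  sweep_grid(dep_sign, curvature_ratios = 1:15,
             blockages = default_blockages(), fcm_values = fcm)
}

#' Run the focusing-voltage sweep
#'
#' Solves the equilibrium root and the focusing-voltage quadrature of the
#' full model for every grid combination and records the collapsed design
#' quantity \eqn{|V^*_{App}| |\mathrm{Re}(f_{CM})| / R^*_C}, which the
#' point-particle model predicts to equal \eqn{1/d^{*2}}. Infeasible
#' combinations (if any) are dropped with a warning and counted in the
#' \code{n_failed} attribute.
#'
#' @param grid a \code{\link{sweep_grid}} or \code{\link{default_grid}}.
#' @param eq_offset,rel_tol passed to \code{\link{focusing_voltage}}.
#' @return A data frame of class \code{cidep_sweep} with columns
#'   \code{dep_sign}, \code{r_c_star}, \code{d_star}, \code{fcm_real},
#'   \code{v_app_abs}, \code{quantity}.
#' @export
#' @examples
#' g <- sweep_grid("negative", 5, c(0.01, 0.05), -0.5)
#' run_sweep(g)
run_sweep <- function(grid, eq_offset = 0.01, rel_tol = 1e-9) {
  if (!inherits(grid, "cidep_sweep_grid"))
    cidep_stop("`grid` must be a sweep_grid()", "invalid_input")
  g <- expand.grid(r_c_star = grid$curvature_ratios,
                   d_star = grid$blockages,
                   fcm_real = grid$fcm_values,
                   KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(rc, d, fcm) {
    tryCatch(focusing_voltage(rc, d, fcm, eq_offset = eq_offset,
                              rel_tol = rel_tol)$v_app_abs,
             cidep_error = function(e) NA_real_)
  }, g$r_c_star, g$d_star, g$fcm_real)
  failed <- is.na(res)
  if (any(failed))
    warning(sprintf("%d grid combination(s) were infeasible and dropped",
                    sum(failed)))
  out <- data.frame(dep_sign = grid$dep_sign,
                    r_c_star = g$r_c_star[!failed],
                    d_star = g$d_star[!failed],
                    fcm_real = g$fcm_real[!failed],
                    v_app_abs = res[!failed])
  out$quantity <- out$v_app_abs * abs(out$fcm_real) / out$r_c_star
  structure(out, n_failed = sum(failed),
            class = c("cidep_sweep", "data.frame"))
}
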