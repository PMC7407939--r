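# Empirical curve fit of the sweep data and the regime classification
# built on it.
#
# The collapsed design quantity Q = |V*App||Re(fCM)|/R*C equals 1/d*^2 in
# the point-particle model; wall repulsion lowers it. The empirical
# correlation has the form Q(d*) = a/d*^2 + b/d* + c.

# Reference empirical coefficients of the C-iDEP focusing correlations
# (a, b, c), one set per DEP sign. These are the canonical published
# design-rule values; running fit_percent_error() on a fresh default-grid
# sweep reproduces b and c to well within 1% (see the methods vignette).
ref_fit_coefficients <- function(dep_sign) {
  dep_sign <- match_dep_sign(dep_sign)
  if (dep_sign == "positive") c(a = 1, b = -1.53, c = 3.36)
  else c(a = 1, b = -2.49, c = 6.75)
}

fit_coefs <- function(fit, dep_sign) {
  if (is.null(fit)) return(ref_fit_coefficients(dep_sign))
  if (inherits(fit, "cidep_fit")) return(c(a = fit$a, b = fit$b, c = fit$c))
  if (is.numeric(fit) && length(fit) == 3L)
    return(c(a = fit[[1]], b = fit[[2]], c = fit[[3]]))
  cidep_stop("`fit` must be NULL, a cidep_fit or a numeric (a, b, c)",
             "invalid_input")
}

eval_quantity <- function(d_star, coefs) {
  coefs[["a"]] / d_star^2 + coefs[["b"]] / d_star + coefs[["c"]]
}

#' Empirical design quantity and focusing voltage
#'
#' Evaluates the empirical correlation
#' \eqn{Q(d^*) = a/d^{*2} + b/d^* + c} for the collapsed design quantity
#' \eqn{|V^*_{App}| |\mathrm{Re}(f_{CM})| / R^*_C}, and the focusing voltage
#' \eqn{|V^*_{App}| = Q(d^*)\, R^*_C / |\mathrm{Re}(f_{CM})|} it implies.
#'
#' @param d_star blockage ratio(s), \eqn{0 < d^* \le 0.15}; vectorised.
#' @param dep_sign \code{"positive"} or \code{"negative"}.
#' @param fit optional \code{\link{fit_percent_error}} result or numeric
#'   \code{c(a, b, c)}; default: the reference coefficients for
#'   \code{dep_sign}.
#' @return Dimensionless quantity (or voltage), same length as
#'   \code{d_star}.
#' @export
#' @examples
#' empirical_voltage(0.08, 5, 0.5, "positive") # 1404.85
empirical_quantity <- function(d_star, dep_sign, fit = NULL) {
  if (any(d_star <= 0 | d_star > 0.15))
    cidep_stop("`d_star` must lie in (0, 0.15]", "invalid_input")
  eval_quantity(d_star, fit_coefs(fit, dep_sign))
}

#' @param curvature_ratio curvature ratio \eqn{R^*_C}.
#' @param fcm_abs \eqn{|\mathrm{Re}(f_{CM})|} (> 0).
#' @rdname empirical_quantity
#' @export
empirical_voltage <- function(d_star, curvature_ratio, fcm_abs, dep_sign,
                              fit = NULL) {
  check_number(curvature_ratio, "curvature_ratio", lower = 0.5,
               strict_lower = TRUE)
  check_number(fcm_abs, "fcm_abs", lower = 0, strict_lower = TRUE, upper = 1)
  empirical_quantity(d_star, dep_sign, fit) * curvature_ratio / fcm_abs
}

#' Percent-error curve fit of sweep records
#'
#' Fits \eqn{Q(d^*) = a/d^{*2} + b/d^* + c} to the collapsed quantity of a
#' sweep by minimising the sum of absolute percentage errors over all
#' records (a derivative-free Nelder-Mead search initialised at
#' \eqn{(a,b,c) = (1,0,0)}). Least squares is deliberately not used: the
#' correlation must stay reliable across four orders of magnitude of
#' \eqn{Q}, and a squared-error objective is dominated by the small-\eqn{d^*}
#' records and misfits the large-blockage end.
#'
#' @param records a \code{\link{run_sweep}} result (or any data frame with
#'   columns \code{d_star} and \code{quantity}; at least 27 distinct
#'   \code{d_star} values).
#' @param fix_leading pin the leading coefficient at \eqn{a = 1} (the
#'   point-particle limit) and fit only \eqn{(b, c)}.
#' @param outlier_cutoff percentage-error cutoff for the outlier count;
#'   default 5 for pDEP records, 8 for nDEP records.
#' @param maxit,restarts optimiser iteration budget and number of
#'   Nelder-Mead restarts from the incumbent.
#' @return An object of class \code{cidep_fit}: list with coefficients
#'   \code{a}, \code{b}, \code{c}, the per-record percentage-error summary
#'   (\code{mean_pct_error}, \code{sd_pct_error}), \code{n_outliers},
#'   \code{outlier_cutoff}, \code{dep_sign} and the optimiser value.
#' @export
#' @examples
#' g <- sweep_grid("negative", 5, c(0.01, 0.03, 0.05), -0.5)
#' \donttest{fit_percent_error(run_sweep(g))}
fit_percent_error <- function(records, fix_leading = FALSE,
                              outlier_cutoff = NULL, maxit = 5000L,
                              restarts = 2L) {
  if (!is.data.frame(records) ||
      !all(c("d_star", "quantity") %in% names(records)))
    cidep_stop("`records` needs columns `d_star` and `quantity`",
               "invalid_input")
  dep_sign <- if ("dep_sign" %in% names(records))
    match_dep_sign(as.character(records$dep_sign[[1]])) else "positive"
  if ("fcm_real" %in% names(records) && nrow(records) > 0)
    dep_sign <- dep_sign_of(records$fcm_real[[1]])
  if (is.null(outlier_cutoff))
    outlier_cutoff <- if (dep_sign == "negative") 8 else 5
  d <- records$d_star
  q <- records$quantity
  pct <- function(coefs) abs((eval_quantity(d, coefs) - q) / q) * 100

  if (fix_leading) {
    obj <- function(p) sum(pct(c(a = 1, b = p[[1]], c = p[[2]])))
    par <- c(0, 0)
  } else {
    obj <- function(p) sum(pct(c(a = p[[1]], b = p[[2]], c = p[[3]])))
    par <- c(1, 0, 0)
  }
  opt <- optim(par, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
  for (i in seq_len(restarts))
    opt <- optim(opt$par, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0)
    cidep_stop(sprintf(
      "percent-error fit failed to converge (code %d, value %g, par %s)",
      opt$convergence, opt$value, paste(signif(opt$par, 6), collapse = ", ")),
      "fit_failure")
  coefs <- if (fix_leading) c(a = 1, b = opt$par[[1]], c = opt$par[[2]]) else
    c(a = opt$par[[1]], b = opt$par[[2]], c = opt$par[[3]])
  errs <- pct(coefs)
  structure(list(a = coefs[["a"]], b = coefs[["b"]], c = coefs[["c"]],
                 mean_pct_error = mean(errs), sd_pct_error = sd(errs),
                 n_outliers = sum(errs > outlier_cutoff),
                 outlier_cutoff = outlier_cutoff, dep_sign = dep_sign,
                 n_records = length(q), objective = opt$value,
                 fix_leading = fix_leading),
            class = "cidep_fit")
}

#' @export
print.cidep_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<percent-error fit, %s DEP> Q(d*) = %.6g/d*^2 %+.6g/d* %+.6g\n",
           "  mean %% error %.3g, sd %.3g, %d/%d records beyond %g%%\n"),
    x$dep_sign, x$a, x$b, x$c, x$mean_pct_error, x$sd_pct_error,
    x$n_outliers, x$n_records, x$outlier_cutoff))
  invisible(x)
}

#' Percentage-error statistics of given coefficients on sweep records
#'
#' Evaluates a coefficient set (by default the reference correlation) on a
#' sweep and summarises the percentage errors, without refitting. Useful to
#' compare an independently recomputed sweep against the reference
#' design-rule coefficients.
#'
#' @inheritParams fit_percent_error
#' @param fit coefficients to evaluate (\code{NULL} = reference set for the
#'   records' DEP sign).
#' @return A list with \code{mean_pct_error}, \code{sd_pct_error},
#'   \code{n_outliers}, \code{outlier_cutoff}.
#' @export
evaluate_fit <- function(records, fit = NULL, outlier_cutoff = NULL) {
  dep_sign <- if ("fcm_real" %in% names(records) && nrow(records) > 0)
    dep_sign_of(records$fcm_real[[1]]) else "positive"
  if (is.null(outlier_cutoff))
    outlier_cutoff <- if (dep_sign == "negative") 8 else 5
  coefs <- fit_coefs(fit, dep_sign)
  errs <- abs((eval_quantity(records$d_star, coefs) - records$quantity) /
                records$quantity) * 100
  list(mean_pct_error = mean(errs), sd_pct_error = sd(errs),
       n_outliers = sum(errs > outlier_cutoff),
       outlier_cutoff = outlier_cutoff)
}

#' Deviation of the empirical correlation from the point-particle solution
#'
#' Percentage deviation
#' \deqn{\delta(d^*) = 100\,\left|\frac{Q_{emp}(d^*) - 1/d^{*2}}
#'   {1/d^{*2}}\right| = 100\,|(a-1) + b\,d^* + c\,d^{*2}|,}
#' which with the reference coefficients reduces to
#' \eqn{100\,|3.36 d^{*2} - 1.53 d^*|} for pDEP and
#' \eqn{100\,|6.75 d^{*2} - 2.49 d^*|} for nDEP. The deviation grows with
#' blockage (wall repulsion strengthens) and is larger for nDEP, whose
#' focusing is assisted by the stronger inner-wall repulsion.
#'
#' @inheritParams empirical_quantity
#' @return Deviation in percent, same length as \code{d_star}.
#' @export
#' @examples
#' deviation_delta(0.0354, "positive") # 5
deviation_delta <- function(d_star, dep_sign, fit = NULL) {
  if (any(d_star <= 0 | d_star > 0.15))
    cidep_stop("`d_star` must lie in (0, 0.15]", "invalid_input")
  coefs <- fit_coefs(fit, dep_sign)
  100 * abs((coefs[["a"]] - 1) + coefs[["b"]] * d_star +
              coefs[["c"]] * d_star^2)
}

#' Particle-size regime boundaries
#'
#' Blockage ratios at which the deviation \eqn{\delta} crosses the regime
#' limits (5\% and 12\% by default), obtained as the smaller positive root
#' of the corresponding deviation quadratic. Below the first boundary
#' (regime 1) the point-particle design rules apply directly; between the
#' boundaries (regime 2) wall repulsion is noticeable; above the second
#' (regime 3) the empirical correlation is required.
#'
#' @param dep_sign \code{"positive"} or \code{"negative"}.
#' @param fit optional coefficients (see \code{\link{empirical_quantity}}).
#' @param limits deviation limits in percent separating the regimes.
#' @return Named numeric vector of boundary \eqn{d^*} values, one per
#'   limit.
#' @export
#' @examples
#' regime_boundaries("positive") # 0.0354 and 0.1007
regime_boundaries <- function(dep_sign, fit = NULL, limits = c(5, 12)) {
  coefs <- fit_coefs(fit, dep_sign)
  vapply(limits, function(lim) {
    # smaller positive root of c d^2 + b d + (a-1) + lim/100 = 0 (the
    # deviation enters through its negative branch: b < 0 for both signs)
    a2 <- coefs[["c"]]
    b2 <- coefs[["b"]]
    c2 <- (coefs[["a"]] - 1) + lim / 100
    disc <- b2^2 - 4 * a2 * c2
    if (disc < 0) return(NA_real_)
    (-b2 - sqrt(disc)) / (2 * a2)
  }, numeric(1)) -> d_bounds
  names(d_bounds) <- paste0("delta_", limits)
  d_bounds
}

#' Classify the particle-size regime
#'
#' @inheritParams empirical_quantity
#' @return A list of class \code{cidep_regime}: \code{regime} (1, 2 or 3),
#'   \code{delta} (percent deviation at \code{d_star}) and
#'   \code{boundaries} (the regime-boundary blockage ratios).
#' @export
#' @examples
#' classify_regime(0.12, "positive")$regime # 3
classify_regime <- function(d_star, dep_sign, fit = NULL) {
  check_number(d_star, "d_star", lower = 0, upper = 0.15,
               strict_lower = TRUE)
  delta <- deviation_delta(d_star, dep_sign, fit)
  regime <- if (delta <= 5) 1L else if (delta <= 12) 2L else 3L
  structure(list(regime = regime, delta = delta,
                 boundaries = regime_boundaries(dep_sign, fit),
                 d_star = d_star, dep_sign = match_dep_sign(dep_sign)),
            class = "cidep_regime")
}

#' @export
print.cidep_regime <- function(x, ...) {
  cat(sprintf(
    "<regime %d> %s DEP, d* = %g, delta = %.4g%% (boundaries: %s)\n",
    x$regime, x$dep_sign, x$d_star, x$delta,
    paste(signif(x$boundaries, 4), collapse = ", ")))
  invisible(x)
}
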