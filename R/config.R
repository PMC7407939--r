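#' Read a design configuration file
#'
#' Reads a YAML or JSON configuration and returns the corresponding
#' \code{\link{dimensionless_design}}. Two layouts are accepted:
#' \itemize{
#'   \item a flat \code{dimensionless} block with fields \code{v_app},
#'     \code{curvature_ratio}, \code{blockage}, \code{fcm_real};
#'   \item nested \code{channel}, \code{drive}, \code{fluid},
#'     \code{particle} blocks with the fields of the corresponding
#'     \code{*_spec()} constructors, converted via
#'     \code{\link{clausius_mossotti}} (unless \code{fcm_real} is given at
#'     the top level) and \code{\link{nondimensionalize}}.
#' }
#' If both layouts are present the flat block wins and a warning is
#' emitted.
#'
#' @param path path to a \code{.yaml}/\code{.yml}/\code{.json} file.
#' @return A \code{\link{dimensionless_design}}.
#' @export
read_design_config <- function(path) {
  if (!file.exists(path))
    cidep_stop(sprintf("config file not found: %s", path), "invalid_config")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  design_from_config(cfg)
}

design_from_config <- function(cfg) {
  has_flat <- !is.null(cfg$dimensionless)
  has_nested <- !is.null(cfg$channel) || !is.null(cfg$particle)
  if (has_flat) {
    if (has_nested)
      warning(paste0("both a `dimensionless` block and dimensional blocks ",
                     "are present; the flat `dimensionless` block takes ",
                     "precedence"))
    dl <- cfg$dimensionless
    need <- c("v_app", "curvature_ratio", "blockage", "fcm_real")
    miss <- setdiff(need, names(dl))
    if (length(miss))
      cidep_stop(sprintf("`dimensionless` block is missing: %s",
                         paste(miss, collapse = ", ")), "invalid_config")
    return(dimensionless_design(dl$v_app, dl$curvature_ratio, dl$blockage,
                                dl$fcm_real))
  }
  if (!has_nested || is.null(cfg$channel) || is.null(cfg$drive) ||
      is.null(cfg$particle))
    cidep_stop(paste0("config needs either a `dimensionless` block or ",
                      "`channel` + `drive` + `particle` blocks"),
               "invalid_config")
  channel <- do.call(channel_spec, cfg$channel)
  drive <- do.call(drive_spec, cfg$drive)
  particle <- do.call(particle_spec, cfg$particle)
  fcm_real <- cfg$fcm_real
  if (is.null(fcm_real)) {
    if (is.null(cfg$fluid))
      cidep_stop(paste0("supply either `fcm_real` or a `fluid` block to ",
                        "compute the Clausius-Mossotti factor"),
                 "invalid_config")
    fluid <- do.call(fluid_spec, cfg$fluid)
    fcm_real <- Re(clausius_mossotti(particle, fluid, drive$frequency))
  }
  nondimensionalize(channel, drive, particle, fcm_real)
}
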