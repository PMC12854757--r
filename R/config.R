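#' Default run configuration
#'
#' The fully-materialized default configuration of the pipeline: every field
#' the subcommands consult has a value here, so a written provenance copy of
#' a resolved configuration is complete and round-trips losslessly.
#'
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    temperature = 300,
    output_dir = "dnakink-out",
    model = list(
      type = "anharmonic",           # "anharmonic" or "harmonic"
      coefficients = "ddd",          # "ddd" or a path to a YAML file
      a_tilt = 0.2, a_roll = 0.056, c_twist = 0.097, g_twistroll = 0.016
    ),
    grid = list(
      rho_max = "25deg", spacing = "2.5deg",
      gammas = c(-0.1, -0.3, -0.5, -0.7, -0.9),
      stiffness_k = 100, exclude_zero = TRUE
    ),
    sampler = list(
      n_samples = 20000L, burn_in = 2000L, proposal_halfwidth = 3,
      domain_bound = 25, thinning = 10L, auto_tune = TRUE
    ),
    wham = list(
      half_range = 95, bin_width = 1, tol = 1e-6, max_iter = 1e5,
      mask_floor = 5
    ),
    fit = list(
      cutoff_quadratic = 3, cutoff_full = 7, refit_cubic = TRUE
    ),
    classify = list(
      roll_min_tb = 20, roll_min_pb = 20, twist_min_tb = 2,
      twist_tol_pb = 5, intrinsic_twist = 34.3
    )
  ), class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration
#'
#' Reads a YAML configuration and materializes every defaulted field (see
#' [default_run_config()]). Unknown top-level sections are rejected to catch
#' typos.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s",
                 paste(unknown, collapse = ", ")))
  structure(merge_config(unclass(cfg), user), class = "run_config")
}

#' Write a run configuration (provenance copy)
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Digest of a resolved configuration
#'
#' MD5 of the serialized YAML text of the fully-resolved configuration;
#' embedded in output files so a result can be matched to the exact settings
#' that produced it.
#'
#' @param config a `run_config`.
#' @return a hex digest string.
#' @export
config_digest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

# Resolve the model section to an energy object.
config_energy <- function(config) {
  m <- config$model
  if (identical(m$type, "harmonic")) {
    harmonic_stiffness(m$a_tilt, m$a_roll, m$c_twist, m$g_twistroll)
  } else if (identical(m$type, "anharmonic")) {
    if (identical(m$coefficients, "ddd")) ddd_coefficients()
    else read_coefficients(m$coefficients)
  } else stop(sprintf("unknown model type '%s'", m$type))
}

config_grid <- function(config) {
  g <- config$grid
  build_window_grid(parse_angle(g$rho_max), parse_angle(g$spacing),
                    as.numeric(g$gammas), stiffness_k = g$stiffness_k,
                    exclude_zero = isTRUE(g$exclude_zero))
}

config_sampler <- function(config) {
  s <- config$sampler
  sampler_settings(n_samples = s$n_samples, burn_in = s$burn_in,
                   proposal_halfwidth = s$proposal_halfwidth,
                   master_seed = config$seed,
                   domain_bound = if (is.null(s$domain_bound) ||
                                      !is.finite(s$domain_bound)) Inf
                                  else s$domain_bound,
                   thinning = s$thinning, auto_tune = isTRUE(s$auto_tune))
}

config_binning <- function(config) {
  default_binning(config$wham$half_range, config$wham$bin_width)
}
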