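#' Unit system for energy bookkeeping
#'
#' All model energies in this package are expressed in units of \eqn{k_B T};
#' bias stiffnesses arrive in kJ/mol per squared radian and are converted
#' through the thermal energy at the given temperature,
#' \eqn{k_B T = 0.0083145 \cdot T} kJ/mol.
#'
#' @param temperature temperature in kelvin (default 300 K).
#' @return an object of class `unit_system` with fields `temperature` and
#'   `kBT` (kJ/mol).
#' @examples
#' u <- unit_system()
#' u$kBT  # 2.49435 kJ/mol at 300 K
#' @export
unit_system <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be a single positive finite number (kelvin)")
  structure(
    list(temperature = temperature, kBT = 0.0083145 * temperature),
    class = "unit_system"
  )
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf("unit_system: T = %g K, kBT = %g kJ/mol\n", x$temperature, x$kBT))
  invisible(x)
}

#' Angle unit conversions
#'
#' @param x numeric vector of angles.
#' @return the converted angles.
#' @name angle-units
NULL

#' @rdname angle-units
#' @export
deg2rad <- function(x) x * (pi / 180)

#' @rdname angle-units
#' @export
rad2deg <- function(x) x * (180 / pi)

#' Parse an angle with an optional unit suffix
#'
#' Accepts strings like `"1.6rad"`, `"-0.3 rad"`, `"91.7deg"` or bare numbers.
#' Bare numbers are interpreted as degrees: internal angle bookkeeping is in
#' degrees throughout, radians are accepted only at configuration boundaries.
#'
#' @param x a number or a single string with optional `rad`/`deg` suffix.
#' @return the angle in degrees.
#' @export
parse_angle <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop("angle must be numeric or a single string")
  s <- trimws(x)
  if (grepl("rad$", s)) {
    v <- suppressWarnings(as.numeric(trimws(sub("rad$", "", s))))
    if (is.na(v)) stop(sprintf("cannot parse angle '%s'", x))
    return(rad2deg(v))
  }
  if (grepl("deg$", s)) {
    v <- suppressWarnings(as.numeric(trimws(sub("deg$", "", s))))
    if (is.na(v)) stop(sprintf("cannot parse angle '%s'", x))
    return(v)
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop(sprintf("cannot parse angle '%s'", x))
  v
}
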