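#' Umbrella-sampling bias window
#'
#' One umbrella window restrains roll and excess twist with the harmonic
#' bias \deqn{V = \tfrac{K}{2}\left[(\rho - \bar\rho)^2 +
#' (\Omega - \gamma\bar\rho)^2\right]} where the squared-angle terms are in
#' radians and `K` is in kJ/mol per squared radian. The twist target is tied
#' to the roll target through the dimensionless slope
#' \eqn{\bar\Omega = \gamma\bar\rho}; it is always recomputed from
#' `rho_bar` and `gamma`, never stored independently.
#'
#' @param rho_bar target roll in degrees.
#' @param gamma dimensionless slope (negative for the standard protocol in
#'   which undertwist accompanies positive roll; any sign is accepted).
#' @param stiffness_k restraint stiffness in kJ/mol per squared radian
#'   (> 0); the same `K` applies to the roll and twist terms.
#' @param window_id stable identifier string; generated from `rho_bar` and
#'   `gamma` when omitted.
#' @return an object of class `bias_window`.
#' @export
bias_window <- function(rho_bar, gamma, stiffness_k = 100,
                        window_id = NULL) {
  if (!is.finite(rho_bar) || !is.finite(gamma))
    stop("rho_bar and gamma must be finite")
  if (!is.finite(stiffness_k) || stiffness_k <= 0)
    stop("stiffness_k must be positive")
  if (is.null(window_id))
    window_id <- sprintf("rho%+08.3f_g%+06.3f", rho_bar, gamma)
  structure(
    list(rho_bar = as.numeric(rho_bar), gamma = as.numeric(gamma),
         stiffness_k = as.numeric(stiffness_k),
         window_id = as.character(window_id)),
    class = "bias_window"
  )
}

#' Derived twist target of a window
#'
#' @param window a [bias_window()].
#' @return \eqn{\bar\Omega = \gamma \bar\rho} in degrees.
#' @export
omega_bar <- function(window) {
  stopifnot(inherits(window, "bias_window"))
  window$gamma * window$rho_bar
}

#' @export
print.bias_window <- function(x, ...) {
  cat(sprintf(
    "bias_window %s: rho_bar = %g deg, gamma = %g (omega_bar = %g deg), K = %g kJ/mol\n",
    x$window_id, x$rho_bar, x$gamma, omega_bar(x), x$stiffness_k))
  invisible(x)
}

#' Bias energy of a window at given step coordinates
#'
#' Evaluates the harmonic restraint of [bias_window()] in \eqn{k_B T}. The
#' stiffness is per squared radian, so coordinates are converted to radians
#' for the squared terms and the result divided by the thermal energy.
#'
#' @param window a [bias_window()].
#' @param coords step coordinates (degrees); tilt is unrestrained.
#' @param units a [unit_system()].
#' @return bias energies in \eqn{k_B T}; zero exactly at the window target.
#' @export
bias_energy <- function(window, coords, units = unit_system()) {
  stopifnot(inherits(window, "bias_window"), inherits(units, "unit_system"))
  coords <- as_step_coords(coords)
  drho <- deg2rad(coords$roll - window$rho_bar)
  domega <- deg2rad(coords$twist_excess - omega_bar(window))
  (window$stiffness_k / 2) * (drho^2 + domega^2) / units$kBT
}

#' Bias stiffness in degree units
#'
#' Converts a restraint stiffness in kJ/mol per squared radian to
#' \eqn{k_B T} per squared degree — the unit in which the sampler and WHAM
#' evaluate the bias.
#'
#' @param stiffness_k kJ/mol per squared radian.
#' @param units a [unit_system()].
#' @return stiffness in \eqn{k_B T} per squared degree.
#' @export
bias_stiffness_deg <- function(stiffness_k, units = unit_system()) {
  (stiffness_k / units$kBT) * (pi / 180)^2
}

#' Build the umbrella window grid
#'
#' Enumerates every (\eqn{\bar\rho}, \eqn{\gamma}) pair on a symmetric roll
#' grid: \eqn{\bar\rho = \pm k \cdot} `spacing` up to `rho_max`, crossed with
#' the slopes in `gammas`. The standard protocol spaces windows 0.1 rad apart
#' on \eqn{-1.6 \le \bar\rho \le 1.6} rad with five negative slopes, dropping
#' the unbiased \eqn{\bar\rho = 0} point (32 windows per slope, 160 total).
#'
#' @param rho_max half-range of the roll grid, degrees (accepts strings with
#'   `rad`/`deg` suffix via [parse_angle()]).
#' @param spacing grid spacing, degrees (or suffixed string).
#' @param gammas numeric vector of slopes (nonempty).
#' @param stiffness_k restraint stiffness, kJ/mol per squared radian.
#' @param exclude_zero drop the \eqn{\bar\rho = 0} windows (default `TRUE`:
#'   the unbiased point adds no umbrella information).
#' @return an object of class `window_grid`: list of [bias_window()] plus
#'   grid metadata.
#' @export
build_window_grid <- function(rho_max, spacing, gammas,
                              stiffness_k = 100, exclude_zero = TRUE) {
  rho_max <- parse_angle(rho_max)
  spacing <- parse_angle(spacing)
  if (!is.numeric(gammas) || length(gammas) == 0L || !all(is.finite(gammas)))
    stop("`gammas` must be a nonempty finite numeric vector")
  if (anyDuplicated(gammas)) stop("`gammas` contains duplicates")
  if (rho_max <= 0 || spacing <= 0)
    stop("rho_max and spacing must be positive")
  n <- floor(rho_max / spacing + 1e-9)
  if (n < 1L)
    stop("spacing larger than rho_max yields an empty grid")
  k <- c(-(n:1), if (!exclude_zero) 0L, 1:n)
  rho_bars <- k * spacing
  windows <- list()
  for (g in gammas)
    for (r in rho_bars)
      windows[[length(windows) + 1L]] <- bias_window(r, g, stiffness_k)
  structure(
    list(windows = windows, rho_max = rho_max, spacing = spacing,
         gammas = as.numeric(gammas), exclude_zero = exclude_zero,
         stiffness_k = stiffness_k),
    class = "window_grid"
  )
}

#' @export
length.window_grid <- function(x) length(x$windows)

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "window_grid: %d windows (%d roll targets x %d slopes), |rho_bar| <= %.4g deg, spacing %.4g deg, K = %g kJ/mol%s\n",
    length(x$windows), length(x$windows) / length(x$gammas),
    length(x$gammas), x$rho_max, x$spacing, x$stiffness_k,
    if (x$exclude_zero) ", rho_bar = 0 excluded" else ""))
  invisible(x)
}

#' @export
as.data.frame.window_grid <- function(x, ...) {
  data.frame(
    window_id = vapply(x$windows, `[[`, character(1), "window_id"),
    rho_bar_deg = vapply(x$windows, `[[`, numeric(1), "rho_bar"),
    gamma = vapply(x$windows, `[[`, numeric(1), "gamma"),
    omega_bar_deg = vapply(x$windows, omega_bar, numeric(1)),
    K_kJmol = vapply(x$windows, `[[`, numeric(1), "stiffness_k")
  )
}

#' Write / read a window grid as a plain-text table
#'
#' Serializes the grid to a whitespace-delimited table with columns
#' `window_id rho_bar_deg gamma omega_bar_deg K_kJmol`.
#'
#' @param grid a `window_grid`.
#' @param path output path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_window_table <- function(grid, path) {
  stopifnot(inherits(grid, "window_grid"))
  df <- as.data.frame(grid)
  lines <- c(
    "# umbrella window grid",
    sprintf("# rho_max_deg %.10g spacing_deg %.10g K_kJmol %.10g exclude_zero %s",
            grid$rho_max, grid$spacing, grid$stiffness_k, grid$exclude_zero),
    paste("window_id", "rho_bar_deg", "gamma", "omega_bar_deg", "K_kJmol"),
    sprintf("%s %.10g %.10g %.10g %.10g", df$window_id, df$rho_bar_deg,
            df$gamma, df$omega_bar_deg, df$K_kJmol)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Protocol bookkeeping summary
#'
#' Summarizes a window grid as simulated: window count, total simulated time
#' and the roll range in degrees. The standard 160-window grid at 1 ns per
#' window totals 0.16 microseconds per sequence.
#'
#' @param grid a `window_grid`.
#' @param time_per_window simulated time per window, ns (> 0).
#' @return a list with `n_windows`, `total_time_us` (microseconds),
#'   `rho_range_deg` (the half-range, i.e. the grid endpoint in degrees).
#' @export
protocol_summary <- function(grid, time_per_window = 1) {
  stopifnot(inherits(grid, "window_grid"))
  if (!is.finite(time_per_window) || time_per_window <= 0)
    stop("time_per_window must be positive (ns)")
  list(
    n_windows = length(grid$windows),
    total_time_us = length(grid$windows) * time_per_window * 1e-3,
    rho_range_deg = grid$rho_max
  )
}
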