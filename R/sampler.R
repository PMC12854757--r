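#' Sampler settings
#'
#' Settings for the Metropolis Monte Carlo surrogate sampler. The sampler
#' draws (roll, excess twist) pairs from the stationary density
#' \eqn{\propto \exp(-\beta[\varepsilon + V])} of a model energy plus a
#' window bias, emulating the statistical structure of biased all-atom
#' trajectories at a desk scale.
#'
#' @param n_samples samples kept per window (> 0).
#' @param burn_in discarded leading samples; default 10% of `n_samples`
#'   (occasional slow relaxation makes a configurable burn-in worthwhile).
#' @param proposal_halfwidth half-width of the uniform square proposal,
#'   degrees; the starting point of the auto-tune pass.
#' @param master_seed integer master seed; per-window seeds are derived
#'   deterministically from it and the window id.
#' @param domain_bound hard-wall half-width in degrees, or `Inf` for an
#'   unbounded domain. Anharmonic surfaces with negative quartics are
#'   non-confining beyond roughly 30 degrees, so sampling them requires a
#'   wall (default 25 degrees there; see [confinement_domain()]).
#' @param thinning keep every `thinning`-th post-burn-in state (default 10,
#'   so kept samples are nearly uncorrelated — emulating the frame stride of
#'   nanosecond-scale biased trajectories rather than raw Metropolis sweeps).
#' @param auto_tune logical; run a short pilot pass adjusting the proposal
#'   half-width toward 30–50% acceptance (pilot samples are discarded).
#' @return an object of class `sampler_settings`.
#' @export
sampler_settings <- function(n_samples = 20000,
                             burn_in = ceiling(0.1 * n_samples),
                             proposal_halfwidth = 3,
                             master_seed = 1L,
                             domain_bound = Inf,
                             thinning = 10L,
                             auto_tune = TRUE) {
  if (!is.finite(n_samples) || n_samples <= 0) stop("n_samples must be > 0")
  if (!is.finite(burn_in) || burn_in < 0) stop("burn_in must be >= 0")
  if (!is.finite(proposal_halfwidth) || proposal_halfwidth <= 0)
    stop("proposal_halfwidth must be > 0")
  if (is.na(domain_bound) || domain_bound <= 0)
    stop("domain_bound must be > 0 (use Inf for unbounded)")
  if (!is.finite(thinning) || thinning < 1) stop("thinning must be >= 1")
  structure(
    list(n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
         proposal_halfwidth = as.numeric(proposal_halfwidth),
         master_seed = as.integer(master_seed),
         domain_bound = as.numeric(domain_bound),
         thinning = as.integer(thinning),
         auto_tune = isTRUE(auto_tune)),
    class = "sampler_settings"
  )
}

#' Deterministic per-window seed
#'
#' Derives a window seed from the master seed and the window id by a small
#' multiplicative string hash (modulo 2^31 - 1), so grids can be re-run
#' partially with identical results.
#'
#' @param master_seed integer.
#' @param window_id character id.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
window_seed <- function(master_seed, window_id) {
  m <- 2147483647
  s <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(as.character(window_id)))
    s <- (s * 31 + code) %% m
  as.integer(s %% (m - 1) + 1)
}

# Map a supported model object to the 10-coefficient polynomial vector
# (a2, c2, g, a3, c3, b, d, a4, c4, h) used by the compiled kernel, or NULL
# if the energy is not polynomial (generic R fallback then applies).
poly_coef_vector <- function(energy) {
  if (inherits(energy, "anharmonic_coefficients")) {
    return(c(energy$a2, energy$c2, energy$g, energy$a3, energy$c3,
             energy$b, energy$d, energy$a4, energy$c4, energy$h))
  }
  if (inherits(energy, "harmonic_stiffness")) {
    # tilt is held at zero in the 2D chain, so a_tilt does not enter
    return(c(energy$a_roll, energy$c_twist, energy$g_twistroll,
             0, 0, 0, 0, 0, 0, 0))
  }
  NULL
}

energy_fun2d <- function(energy) {
  if (is.function(energy)) return(energy)
  if (inherits(energy, "anharmonic_coefficients"))
    return(function(coords) eval_anharmonic(coords, energy))
  if (inherits(energy, "harmonic_stiffness"))
    return(function(coords) eval_harmonic(coords, energy))
  stop("`energy` must be a harmonic_stiffness, anharmonic_coefficients, ",
       "or a function of step coordinates returning kBT")
}

# Pure-R Metropolis chain for arbitrary energy functions (slow path).
mcmc_chain_r <- function(efun, rho_bar, omega_bar, k_deg, bound, halfwidth,
                         n_keep, burn_in, thin, rho0, omega0) {
  e_at <- function(r, w)
    efun(step_coords(0, r, w)) +
      0.5 * k_deg * ((r - rho_bar)^2 + (w - omega_bar)^2)
  r <- rho0; w <- omega0; e <- e_at(r, w)
  total <- burn_in + n_keep * thin
  out_r <- numeric(n_keep); out_w <- numeric(n_keep)
  kept <- 0L; n_acc <- 0L
  for (i in seq_len(total)) {
    rp <- r + stats::runif(1, -halfwidth, halfwidth)
    wp <- w + stats::runif(1, -halfwidth, halfwidth)
    inside <- !is.finite(bound) || (abs(rp) <= bound && abs(wp) <= bound)
    if (inside) {
      ep <- e_at(rp, wp)
      if (ep <= e || stats::runif(1) < exp(e - ep)) {
        r <- rp; w <- wp; e <- ep; n_acc <- n_acc + 1L
      }
    }
    if (i > burn_in && (i - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out_r[kept] <- r; out_w[kept] <- w
    }
  }
  list(roll = out_r, twist_excess = out_w,
       acceptance_rate = n_acc / total)
}

run_chain <- function(energy, rho_bar, omega_bar, k_deg, bound, halfwidth,
                      n_keep, burn_in, thin, rho0, omega0) {
  coef <- poly_coef_vector(energy)
  if (!is.null(coef)) {
    .mcmc_kernel(coef, rho_bar, omega_bar, k_deg,
                 if (is.finite(bound)) bound else -1,
                 halfwidth, as.integer(n_keep), as.integer(burn_in),
                 as.integer(thin), rho0, omega0)
  } else {
    mcmc_chain_r(energy_fun2d(energy), rho_bar, omega_bar, k_deg, bound,
                 halfwidth, n_keep, burn_in, thin, rho0, omega0)
  }
}

#' Sample one umbrella window by Metropolis Monte Carlo
#'
#' Runs a Metropolis chain over (roll, excess twist) with symmetric uniform
#' square proposals, stationary density proportional to
#' \eqn{\exp(-\beta[\varepsilon + V])} where \eqn{V} is the window bias.
#' Proposals outside the hard-wall domain are rejected. An auto-tune pass
#' (discarded) adjusts the proposal half-width toward 30–50% acceptance.
#' Identical inputs and master seed give bit-identical trajectories.
#'
#' @param energy a [harmonic_stiffness()], [anharmonic_coefficients()], or a
#'   function of step coordinates returning energies in \eqn{k_B T}.
#' @param window a [bias_window()], or `NULL` for an unbiased run.
#' @param settings a [sampler_settings()].
#' @param units a [unit_system()].
#' @return an object of class `window_trajectory`: fields `window`, `samples`
#'   (a [step_coords()] data.frame), `time` (sample index), `broken` (logical
#'   flags, all `FALSE` until [mark_broken()]), `seed_used`,
#'   `acceptance_rate`, `proposal_halfwidth`.
#' @export
sample_window <- function(energy, window, settings = sampler_settings(),
                          units = unit_system()) {
  stopifnot(inherits(settings, "sampler_settings"),
            inherits(units, "unit_system"))
  if (is.null(window)) {
    window <- NULL
    rho_bar <- 0; om_bar <- 0; k_deg <- 0
    wid <- "unbiased"
  } else {
    stopifnot(inherits(window, "bias_window"))
    rho_bar <- window$rho_bar
    om_bar <- omega_bar(window)
    k_deg <- bias_stiffness_deg(window$stiffness_k, units)
    wid <- window$window_id
  }
  bound <- settings$domain_bound
  clamp <- function(x) if (is.finite(bound)) max(-bound, min(bound, x)) else x
  rho0 <- clamp(rho_bar); omega0 <- clamp(om_bar)

  seed <- window_seed(settings$master_seed, wid)
  hw <- settings$proposal_halfwidth
  res <- withr::with_seed(seed, {
    if (settings$auto_tune) {
      for (i in 1:15) {
        pilot <- run_chain(energy, rho_bar, om_bar, k_deg, bound, hw,
                           n_keep = 400, burn_in = 100, thin = 1,
                           rho0 = rho0, omega0 = omega0)
        acc <- pilot$acceptance_rate
        if (acc > 0.5) hw <- hw * 1.6
        else if (acc < 0.3) hw <- hw / 1.6
        else break
      }
    }
    run_chain(energy, rho_bar, om_bar, k_deg, bound, hw,
              n_keep = settings$n_samples, burn_in = settings$burn_in,
              thin = settings$thinning, rho0 = rho0, omega0 = omega0)
  })
  if (res$acceptance_rate < 0.05 || res$acceptance_rate > 0.95)
    warning(sprintf(
      "window %s: acceptance rate %.3f outside [0.05, 0.95] after tuning",
      wid, res$acceptance_rate))
  structure(
    list(window = window,
         samples = step_coords(0, res$roll, res$twist_excess),
         time = seq_along(res$roll) - 1L,
         broken = rep(FALSE, length(res$roll)),
         seed_used = seed,
         acceptance_rate = res$acceptance_rate,
         proposal_halfwidth = hw),
    class = "window_trajectory"
  )
}

#' @export
print.window_trajectory <- function(x, ...) {
  wid <- if (is.null(x$window)) "unbiased" else x$window$window_id
  cat(sprintf(
    "window_trajectory %s: %d samples (%d flagged broken), acceptance %.2f, seed %d\n",
    wid, nrow(x$samples), sum(x$broken), x$acceptance_rate, x$seed_used))
  invisible(x)
}

#' Run the full umbrella protocol with the surrogate sampler
#'
#' One trajectory per window of the grid, each with an independent seed
#' derived from the master seed and the window id; output order matches the
#' grid order. A window whose chain fails is recorded with a warning and
#' skipped; the run continues.
#'
#' @inheritParams sample_window
#' @param grid a `window_grid` from [build_window_grid()].
#' @return a list of `window_trajectory` objects (class
#'   `trajectory_set`); failed windows are dropped and named in a
#'   `failed_windows` attribute.
#' @export
run_protocol <- function(energy, grid, settings = sampler_settings(),
                         units = unit_system()) {
  stopifnot(inherits(grid, "window_grid"))
  out <- list()
  failed <- character(0)
  for (w in grid$windows) {
    traj <- tryCatch(sample_window(energy, w, settings, units),
                     error = function(e) {
                       warning(sprintf("window %s failed: %s", w$window_id,
                                       conditionMessage(e)))
                       NULL
                     })
    if (is.null(traj)) failed <- c(failed, w$window_id)
    else out[[length(out) + 1L]] <- traj
  }
  attr(out, "failed_windows") <- failed
  class(out) <- c("trajectory_set", "list")
  out
}

#' Flag broken samples in a trajectory
#'
#' Applies a breakage-surrogate rule — a predicate over step coordinates —
#' and sets the `broken` flags where it fires. In biased all-atom runs,
#' biases beyond a sequence-dependent threshold disrupt the central base
#' pairs, and such samples are excluded from free-energy estimation; the
#' histogram builder honours these flags. The bundled rule is a configurable
#' surrogate, not a structural criterion.
#'
#' @param traj a `window_trajectory`.
#' @param rule a function mapping a [step_coords()] data.frame to a logical
#'   vector (`TRUE` = broken), e.g. the complement of
#'   [confinement_domain()].
#' @return the trajectory with updated `broken` flags.
#' @export
mark_broken <- function(traj, rule) {
  stopifnot(inherits(traj, "window_trajectory"), is.function(rule))
  flags <- rule(traj$samples)
  if (!is.logical(flags) || length(flags) != nrow(traj$samples))
    stop("rule must return one logical per sample")
  traj$broken <- traj$broken | flags
  traj
}
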