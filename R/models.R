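#' Base-pair-step coordinates
#'
#' The coordinate space of the whole pipeline: one base-pair step's tilt,
#' roll and excess twist, in degrees. Excess twist is relative to the
#' intrinsic helical twist, so an undeformed step is (0, 0, 0).
#'
#' @param tilt,roll,twist_excess numeric vectors (degrees), recycled to a
#'   common length.
#' @return a data.frame of class `step_coords` with columns `tilt`, `roll`,
#'   `twist_excess`.
#' @export
step_coords <- function(tilt = 0, roll = 0, twist_excess = 0) {
  n <- max(length(tilt), length(roll), length(twist_excess))
  out <- data.frame(
    tilt = rep_len(as.numeric(tilt), n),
    roll = rep_len(as.numeric(roll), n),
    twist_excess = rep_len(as.numeric(twist_excess), n)
  )
  if (!all(vapply(out, function(col) all(is.finite(col)), logical(1))))
    stop("step coordinates must be finite")
  class(out) <- c("step_coords", "data.frame")
  out
}

as_step_coords <- function(x) {
  if (inherits(x, "step_coords")) return(x)
  if (is.data.frame(x)) {
    need <- c("tilt", "roll", "twist_excess")
    if (!all(need %in% names(x)))
      stop("data.frame must have columns tilt, roll, twist_excess")
    return(step_coords(x$tilt, x$roll, x$twist_excess))
  }
  if (is.numeric(x) && length(x) == 3L)
    return(step_coords(x[1], x[2], x[3]))
  stop("cannot interpret input as step coordinates")
}

#' Harmonic rigid-base stiffness
#'
#' Stiffness parameters of the quadratic rigid-base energy in tilt, roll and
#' excess twist, in \eqn{k_B T} per squared degree. The roll/twist block must
#' be positive definite; the dominant off-diagonal interaction is the
#' twist-roll coupling `g_twistroll`.
#'
#' @param a_tilt,a_roll,c_twist diagonal stiffnesses (> 0).
#' @param g_twistroll twist-roll coupling; requires
#'   `a_roll * c_twist > g_twistroll^2`.
#' @return an object of class `harmonic_stiffness`.
#' @export
harmonic_stiffness <- function(a_tilt, a_roll, c_twist, g_twistroll = 0) {
  v <- c(a_tilt = a_tilt, a_roll = a_roll, c_twist = c_twist,
         g_twistroll = g_twistroll)
  if (!all(is.finite(v))) stop("stiffnesses must be finite")
  if (a_tilt <= 0 || a_roll <= 0 || c_twist <= 0)
    stop("diagonal stiffnesses must be positive")
  if (a_roll * c_twist <= g_twistroll^2)
    stop("roll/twist stiffness block is not positive definite")
  structure(as.list(v), class = "harmonic_stiffness")
}

#' @export
print.harmonic_stiffness <- function(x, ...) {
  cat("harmonic_stiffness (kBT / deg^2):\n")
  cat(sprintf("  a_tilt = %g, a_roll = %g, c_twist = %g, g_twistroll = %g\n",
              x$a_tilt, x$a_roll, x$c_twist, x$g_twistroll))
  invisible(x)
}

#' Anharmonic surface coefficients
#'
#' Coefficient set of the anharmonic roll/twist free-energy surface
#' \deqn{\beta\varepsilon = \tfrac12 (a_2\rho^2 + c_2\Omega^2 + 2g\Omega\rho
#'   + a_3\rho^3 + c_3\Omega^3 + b\rho^2\Omega + d\rho\Omega^2
#'   + a_4\rho^4 + c_4\Omega^4 + h\rho^2\Omega^2)}
#' with angles in degrees and energies in \eqn{k_B T}. Coefficients are stored
#' on their natural (unscaled) values; printed tables in the field typically
#' quote the quadratic block times 1e2, the cubic block times 1e4 and the
#' quartic block times 1e5 — those factors are applied at parse/display time,
#' never stored.
#'
#' @param a2,c2,g quadratic block (must be positive definite: `a2*c2 > g^2`).
#' @param a3,c3,b,d cubic block.
#' @param a4,c4,h quartic block (`rho^3*Omega` and `rho*Omega^3` are never
#'   part of the model).
#' @param fit_cutoff_quadratic,fit_cutoff_full free-energy cutoffs in
#'   \eqn{k_B T} bounding the regions where the quadratic and the full model
#'   are intended to be fitted.
#' @return an object of class `anharmonic_coefficients`.
#' @export
anharmonic_coefficients <- function(a2, c2, g = 0,
                                    a3 = 0, c3 = 0, b = 0, d = 0,
                                    a4 = 0, c4 = 0, h = 0,
                                    fit_cutoff_quadratic = 3,
                                    fit_cutoff_full = 7) {
  v <- c(a2 = a2, c2 = c2, g = g, a3 = a3, c3 = c3, b = b, d = d,
         a4 = a4, c4 = c4, h = h)
  if (!all(is.finite(v))) stop("coefficients must be finite")
  if (a2 <= 0 || c2 <= 0 || a2 * c2 <= g^2)
    stop("quadratic block is not positive definite")
  structure(
    c(as.list(v), list(fit_cutoff_quadratic = fit_cutoff_quadratic,
                       fit_cutoff_full = fit_cutoff_full)),
    class = "anharmonic_coefficients"
  )
}

#' @export
print.anharmonic_coefficients <- function(x, ...) {
  cat("anharmonic_coefficients (kBT, degrees; printed scales re-applied):\n")
  cat(sprintf("  quadratic x 1e2:  a2 = %g, c2 = %g, g = %g\n",
              1e2 * x$a2, 1e2 * x$c2, 1e2 * x$g))
  cat(sprintf("  cubic     x 1e4:  a3 = %g, c3 = %g, b = %g, d = %g\n",
              1e4 * x$a3, 1e4 * x$c3, 1e4 * x$b, 1e4 * x$d))
  cat(sprintf("  quartic   x 1e5:  a4 = %g, c4 = %g, h = %g\n",
              1e5 * x$a4, 1e5 * x$c4, 1e5 * x$h))
  cat(sprintf("  fit cutoffs: quadratic <= %g kBT, full <= %g kBT\n",
              x$fit_cutoff_quadratic, x$fit_cutoff_full))
  invisible(x)
}

#' Harmonic rigid-base energy of a step
#'
#' Evaluates \eqn{\beta\varepsilon = \tfrac12 (A^\tau \tau^2 + A^\rho \rho^2
#' + C \Omega^2 + 2 G \Omega \rho)} per step, in \eqn{k_B T}. Symmetric under
#' simultaneous sign change of all coordinates.
#'
#' @param coords a [step_coords()] object (or coercible data.frame).
#' @param stiff a [harmonic_stiffness()] object.
#' @return numeric vector of energies in \eqn{k_B T}, one per row of `coords`.
#' @examples
#' s <- harmonic_stiffness(a_tilt = 0.2, a_roll = 0.056,
#'                         c_twist = 0.097, g_twistroll = 0.016)
#' eval_harmonic(step_coords(0, 10, 0), s)  # 2.8 kBT
#' @export
eval_harmonic <- function(coords, stiff) {
  coords <- as_step_coords(coords)
  stopifnot(inherits(stiff, "harmonic_stiffness"))
  0.5 * (stiff$a_tilt * coords$tilt^2 +
         stiff$a_roll * coords$roll^2 +
         stiff$c_twist * coords$twist_excess^2 +
         2 * stiff$g_twistroll * coords$twist_excess * coords$roll)
}

#' Anharmonic roll/twist energy of a step
#'
#' Evaluates the cubic/quartic surface (see [anharmonic_coefficients()]) in
#' \eqn{k_B T}. Tilt is carried in the coordinate type but does not enter:
#' it is a much stiffer degree of freedom and is neglected in the anharmonic
#' description of kinks. The global 1/2 multiplies every term.
#'
#' @inheritParams eval_harmonic
#' @param coeffs an [anharmonic_coefficients()] object.
#' @return numeric vector of energies in \eqn{k_B T}.
#' @export
eval_anharmonic <- function(coords, coeffs) {
  coords <- as_step_coords(coords)
  stopifnot(inherits(coeffs, "anharmonic_coefficients"))
  r <- coords$roll
  w <- coords$twist_excess
  0.5 * (coeffs$a2 * r^2 + coeffs$c2 * w^2 + 2 * coeffs$g * w * r +
         coeffs$a3 * r^3 + coeffs$c3 * w^3 + coeffs$b * r^2 * w +
         coeffs$d * r * w^2 +
         coeffs$a4 * r^4 + coeffs$c4 * w^4 + coeffs$h * r^2 * w^2)
}

#' One-dimensional phenomenological bending models
#'
#' Constructs a 1D bending-energy model \eqn{g(\theta)} of one of four
#' variants commonly used to describe kinkable DNA:
#' \describe{
#'   \item{harmonic}{\eqn{g_1 \theta^2 / 2}, wormlike-chain elasticity.}
#'   \item{subelastic}{\eqn{\alpha |\theta|}, the linear subelastic chain.}
#'   \item{hinge}{\eqn{\min(g_1\theta^2/2,\; h + (g_2/2)(\theta-\theta_0)^c)},
#'     a harmonic branch plus a kinked branch offset by the kink cost `h`;
#'     exponent `c` is 2 or 6.}
#'   \item{two_state}{a fluctuating two-state (B-DNA vs locally melted) model
#'     with \eqn{g(\theta,0)=a\theta^2} and \eqn{g(\theta,1)=a'\theta^2+\mu},
#'     \eqn{a' \le a}; evaluated by default as the free energy
#'     \eqn{-\ln(e^{-a\theta^2} + e^{-a'\theta^2-\mu})} (log-sum-exp over the
#'     melt state), optionally as the ground-state minimum over branches.}
#' }
#'
#' @param variant one of `"harmonic"`, `"subelastic"`, `"hinge"`,
#'   `"two_state"`.
#' @param g1,alpha,h,g2,theta0,c_exponent,a,a_prime,mu variant parameters;
#'   angles in degrees, energies in \eqn{k_B T}.
#' @return an object of class `bend1d_model`.
#' @export
bend1d_model <- function(variant = c("harmonic", "subelastic", "hinge",
                                     "two_state"),
                         g1 = NULL, alpha = NULL,
                         h = NULL, g2 = NULL, theta0 = NULL, c_exponent = 2,
                         a = NULL, a_prime = NULL, mu = NULL) {
  variant <- match.arg(variant)
  chk_nonneg <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x < 0)
      stop(sprintf("'%s' must be a finite nonnegative number for variant '%s'",
                   nm, variant))
    x
  }
  pars <- switch(variant,
    harmonic = list(g1 = chk_nonneg(g1, "g1")),
    subelastic = list(alpha = chk_nonneg(alpha, "alpha")),
    hinge = {
      if (!c_exponent %in% c(2, 6))
        stop("hinge exponent c must be 2 or 6")
      list(g1 = chk_nonneg(g1, "g1"), h = chk_nonneg(h, "h"),
           g2 = chk_nonneg(g2, "g2"),
           theta0 = if (is.null(theta0) || !is.finite(theta0))
             stop("'theta0' must be finite") else theta0,
           c_exponent = c_exponent)
    },
    two_state = {
      a <- chk_nonneg(a, "a"); a_prime <- chk_nonneg(a_prime, "a_prime")
      if (a_prime > a) stop("two-state model requires a_prime <= a")
      list(a = a, a_prime = a_prime,
           mu = if (is.null(mu) || !is.finite(mu))
             stop("'mu' must be finite") else mu)
    })
  structure(list(variant = variant, parameters = pars),
            class = "bend1d_model")
}

#' @export
print.bend1d_model <- function(x, ...) {
  cat(sprintf("bend1d_model: variant '%s'\n", x$variant))
  p <- x$parameters
  cat(" ", paste(sprintf("%s = %g", names(p), unlist(p)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Evaluate a 1D bending model
#'
#' @param theta bending angle(s) in degrees.
#' @param model a [bend1d_model()].
#' @param ground_state for the two-state variant only: if `TRUE`, evaluate
#'   the ground-state minimum over the two branches instead of the default
#'   free-energy marginalization over the fluctuating melt state.
#' @return energies in \eqn{k_B T}.
#' @export
eval_bend1d <- function(theta, model, ground_state = FALSE) {
  stopifnot(inherits(model, "bend1d_model"))
  if (!all(is.finite(theta))) stop("theta must be finite")
  p <- model$parameters
  switch(model$variant,
    harmonic = p$g1 * theta^2 / 2,
    subelastic = p$alpha * abs(theta),
    hinge = pmin(p$g1 * theta^2 / 2,
                 p$h + (p$g2 / 2) * (theta - p$theta0)^p$c_exponent),
    two_state = {
      e0 <- p$a * theta^2
      e1 <- p$a_prime * theta^2 + p$mu
      if (ground_state) {
        pmin(e0, e1)
      } else {
        # log-sum-exp, stabilized, shifted so g(0) = -ln(1 + e^-mu) ... no:
        # free energy is defined up to a constant; report relative to theta
        # independent reference -ln(sum) directly (g(0) = -ln(1+e^-mu) != 0),
        # then shift so that g(0) = 0 to keep the origin convention.
        lse <- function(x, y) {
          m <- pmin(x, y)
          m - log1p(exp(-abs(x - y)))
        }
        lse(e0, e1) - lse(0, p$mu)
      }
    })
}

#' Confinement domain for non-confining anharmonic surfaces
#'
#' Anharmonic surfaces with negative quartic coefficients turn over at large
#' deformations and describe the free-energy manifold of unbroken
#' conformations only on a finite range of |roll| and |twist|. This returns
#' a membership predicate used as the sampler's hard wall.
#'
#' @param coeffs an [anharmonic_coefficients()] object (unused by the test
#'   itself but documents which surface the wall belongs to).
#' @param bound positive half-width of the square domain, degrees.
#' @return a function mapping step coordinates to a logical vector, `TRUE`
#'   inside the domain.
#' @export
confinement_domain <- function(coeffs, bound) {
  stopifnot(inherits(coeffs, "anharmonic_coefficients"))
  if (!is.numeric(bound) || length(bound) != 1L || !is.finite(bound) ||
      bound <= 0)
    stop("`bound` must be a single positive number (degrees)")
  force(bound)
  function(coords) {
    coords <- as_step_coords(coords)
    abs(coords$roll) <= bound & abs(coords$twist_excess) <= bound
  }
}
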