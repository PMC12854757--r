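#' Gradient of the anharmonic surface
#'
#' Analytic partial derivatives of the polynomial roll/twist energy with
#' respect to roll and excess twist, in \eqn{k_B T} per degree.
#'
#' @param coords step coordinates.
#' @param coeffs an [anharmonic_coefficients()] object.
#' @return a two-column matrix `(d_roll, d_twist)`.
#' @export
anharmonic_gradient <- function(coords, coeffs) {
  coords <- as_step_coords(coords)
  stopifnot(inherits(coeffs, "anharmonic_coefficients"))
  r <- coords$roll
  w <- coords$twist_excess
  dr <- 0.5 * (2 * coeffs$a2 * r + 2 * coeffs$g * w +
               3 * coeffs$a3 * r^2 + 2 * coeffs$b * r * w + coeffs$d * w^2 +
               4 * coeffs$a4 * r^3 + 2 * coeffs$h * r * w^2)
  dw <- 0.5 * (2 * coeffs$c2 * w + 2 * coeffs$g * r +
               3 * coeffs$c3 * w^2 + coeffs$b * r^2 + 2 * coeffs$d * r * w +
               4 * coeffs$c4 * w^3 + 2 * coeffs$h * r^2 * w)
  cbind(d_roll = dr, d_twist = dw)
}

#' Breakage surrogate: runaway side of the free-energy ridge
#'
#' An anharmonic surface with negative quartics describes the free-energy
#' manifold of unbroken conformations only within a finite range: beyond a
#' ridge the polynomial runs downhill toward ever larger deformations, where
#' real biased trajectories disrupt base pairing. This rule flags a sample as
#' broken when the surface decreases outward at its position — when the
#' radial directional derivative \eqn{\hat{x} \cdot \nabla\varepsilon} is
#' negative — i.e. when the sample sits on the runaway side of the ridge.
#' It is a model-intrinsic surrogate for a structural base-pair-breakage
#' criterion, with no free threshold.
#'
#' @param coeffs the [anharmonic_coefficients()] of the generating surface.
#' @return a predicate over step coordinates suitable for [mark_broken()]:
#'   returns `TRUE` where the sample is past the ridge.
#' @export
breakage_rule_radial <- function(coeffs) {
  stopifnot(inherits(coeffs, "anharmonic_coefficients"))
  force(coeffs)
  function(coords) {
    coords <- as_step_coords(coords)
    gr <- anharmonic_gradient(coords, coeffs)
    rad <- coords$roll * gr[, "d_roll"] +
           coords$twist_excess * gr[, "d_twist"]
    rad < 0
  }
}
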