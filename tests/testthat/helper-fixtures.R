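# Shared fixtures: the reference coefficient set, a matching harmonic
# stiffness, and small random positive-definite stiffness generators.

ddd <- ddd_coefficients()

hs_ref <- harmonic_stiffness(a_tilt = 0.2, a_roll = 0.056,
                             c_twist = 0.097, g_twistroll = 0.016)

units300 <- unit_system(300)

# analytic covariance of the (roll, twist) block: inverse stiffness in kBT
analytic_cov <- function(hs) {
  m <- matrix(c(hs$a_roll, hs$g_twistroll, hs$g_twistroll, hs$c_twist), 2)
  solve(m)
}

# random positive-definite roll/twist stiffness (tilt fixed stiff)
random_stiffness <- function() {
  a <- stats::runif(1, 0.03, 0.15)
  c <- stats::runif(1, 0.03, 0.15)
  g <- stats::runif(1, -0.5, 0.5) * sqrt(a * c)
  harmonic_stiffness(0.2, a, c, g)
}

# a tiny hand-built trajectory around given samples (no sampling involved)
manual_trajectory <- function(roll, twist, window = NULL) {
  structure(
    list(window = window, samples = step_coords(0, roll, twist),
         time = seq_along(roll) - 1L,
         broken = rep(FALSE, length(roll)),
         seed_used = 0L, acceptance_rate = 1, proposal_halfwidth = 1),
    class = "window_trajectory"
  )
}
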