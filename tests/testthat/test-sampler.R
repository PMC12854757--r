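test_that("identical master seed gives bit-identical trajectories", {
  w <- bias_window(10, -0.5, 100)
  st <- sampler_settings(n_samples = 2000, master_seed = 99)
  t1 <- sample_window(hs_ref, w, st, units300)
  t2 <- sample_window(hs_ref, w, st, units300)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$seed_used, t2$seed_used)
  # different windows get different derived seeds
  w2 <- bias_window(-10, -0.5, 100)
  t3 <- sample_window(hs_ref, w2, st, units300)
  expect_false(t3$seed_used == t1$seed_used)
  expect_true(t1$seed_used >= 1 && t1$seed_used < 2^31)
})

test_that("unbiased harmonic sampling reproduces the inverse-stiffness covariance", {
  st <- sampler_settings(n_samples = 1e5, master_seed = 42)
  tr <- sample_window(hs_ref, NULL, st, units300)
  cv <- analytic_cov(hs_ref)
  expect_equal(stats::var(tr$samples$roll), cv[1, 1], tolerance = 0.05)
  expect_equal(stats::var(tr$samples$twist_excess), cv[2, 2],
               tolerance = 0.05)
  expect_equal(stats::cov(tr$samples$roll, tr$samples$twist_excess),
               cv[1, 2], tolerance = 0.10)
  # and for 3 random positive-definite stiffness sets
  withr::with_seed(2024, sets <- replicate(3, random_stiffness(),
                                           simplify = FALSE))
  for (i in seq_along(sets)) {
    sti <- sampler_settings(n_samples = 1e5, master_seed = 100 + i)
    tri <- sample_window(sets[[i]], NULL, sti, units300)
    cvi <- analytic_cov(sets[[i]])
    expect_equal(stats::var(tri$samples$roll), cvi[1, 1], tolerance = 0.05)
    expect_equal(stats::var(tri$samples$twist_excess), cvi[2, 2],
                 tolerance = 0.05)
  }
})

test_that("a very stiff restraint pins the chain to the window target", {
  w <- bias_window(15, -0.6, 50000)
  st <- sampler_settings(n_samples = 5000, master_seed = 5)
  tr <- sample_window(hs_ref, w, st, units300)
  expect_equal(mean(tr$samples$roll), 15, tolerance = 0.02)
  expect_equal(mean(tr$samples$twist_excess), -9, tolerance = 0.03)
})

test_that("mean roll is attenuated relative to the bias target in every window", {
  grid <- build_window_grid(20, 5, c(-0.1, -0.7), stiffness_k = 100)
  st <- sampler_settings(n_samples = 5000, master_seed = 8)
  trajs <- run_protocol(hs_ref, grid, st, units300)
  expect_length(trajs, length(grid$windows))
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    expect_lt(abs(mean(tr$samples$roll)), abs(tr$window$rho_bar))
  }
})

test_that("the chain is reversible: coarse-grained detailed balance holds", {
  # discretize roll into 3 states and compare empirical transition flows
  st <- sampler_settings(n_samples = 2e5, master_seed = 31, thinning = 1,
                         auto_tune = FALSE, proposal_halfwidth = 6)
  tr <- sample_window(hs_ref, NULL, st, units300)
  state <- cut(tr$samples$roll, c(-Inf, -3, 3, Inf), labels = FALSE)
  n <- length(state)
  trans <- table(factor(state[-n], levels = 1:3),
                 factor(state[-1], levels = 1:3))
  for (i in 1:2) for (j in (i + 1):3) {
    nij <- trans[i, j]; nji <- trans[j, i]
    # flows i->j and j->i are equal within ~4 sd of a Poisson difference
    expect_lt(abs(nij - nji), 4 * sqrt(nij + nji) + 1)
  }
})

test_that("reweighting a single biased window recovers unbiased moments", {
  w <- bias_window(8, -0.5, 200)
  st <- sampler_settings(n_samples = 1e5, master_seed = 17)
  tr <- sample_window(hs_ref, w, st, units300)
  lw <- bias_energy(w, tr$samples, units300)     # +beta*V reweighting
  wt <- exp(lw - max(lw))
  wt <- wt / sum(wt)
  m_rho <- sum(wt * tr$samples$roll)
  v_rho <- sum(wt * (tr$samples$roll - m_rho)^2)
  cv <- analytic_cov(hs_ref)
  expect_equal(m_rho, 0, tolerance = 0.3)
  expect_equal(v_rho, cv[1, 1], tolerance = 0.1)
})

test_that("hard wall confines samples and broken marking flags by rule", {
  st <- sampler_settings(n_samples = 5000, master_seed = 12,
                         domain_bound = 25)
  w <- bias_window(25, -0.9, 100)
  tr <- sample_window(ddd, w, st, units300)
  expect_true(all(abs(tr$samples$roll) <= 25))
  expect_true(all(abs(tr$samples$twist_excess) <= 25))
  # rule that never fires on a confined chain
  tr2 <- mark_broken(tr, function(s) abs(s$roll) > 25)
  expect_equal(sum(tr2$broken), 0)
  # always-true rule: downstream histograms are empty
  tr3 <- mark_broken(tr, function(s) rep(TRUE, nrow(s)))
  expect_true(all(tr3$broken))
  expect_error(build_histograms(list(tr3), default_binning()),
               "no usable samples")
})

test_that("Gaussian tail exclusion rule fires at the expected (tiny) rate", {
  # unbiased harmonic chain: sd(omega) ~ 3.3 deg, so P(|omega| > 20) is
  # below 1e-9; at 1e5 samples the flagged fraction must be < 1e-4
  st <- sampler_settings(n_samples = 1e5, master_seed = 23)
  tr <- sample_window(hs_ref, NULL, st, units300)
  tr <- mark_broken(tr, function(s) abs(s$twist_excess) > 20)
  expect_lt(mean(tr$broken), 1e-4)
})

test_that("breakage surrogate flags exactly the runaway side of the ridge", {
  rule <- breakage_rule_radial(ddd)
  # well inside the basin: unbroken
  expect_false(any(rule(step_coords(0, c(0, 5, -10, 15), c(0, -5, 5, -10)))))
  # past the corner ridge where the surface runs downhill: broken
  expect_true(all(rule(step_coords(0, c(25, 24), c(-25, -24)))))
})

test_that("failed windows are skipped and recorded, run continues", {
  grid <- build_window_grid(10, 5, -0.5)
  bad_energy <- function(coords) {
    if (any(coords$roll > 7)) stop("synthetic failure")
    eval_harmonic(coords, hs_ref)
  }
  st <- sampler_settings(n_samples = 200, master_seed = 3, auto_tune = FALSE)
  trajs <- suppressWarnings(run_protocol(bad_energy, grid, st, units300))
  expect_lt(length(trajs), length(grid$windows))
  expect_gt(length(attr(trajs, "failed_windows")), 0)
})
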