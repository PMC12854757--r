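test_that("histogram building obeys the half-open bin convention", {
  bn <- binning2d(c(0, 1, 2, 3), c(0, 1, 2, 3))
  # four samples in one bin
  tr <- manual_trajectory(rep(0.5, 4), rep(0.5, 4))
  st <- build_histograms(list(tr), bn)
  expect_equal(sum(st$counts), 4)
  expect_equal(max(st$counts), 4)
  # a sample exactly on an interior edge goes to the right-hand bin
  tr2 <- manual_trajectory(1, 0.5)
  st2 <- build_histograms(list(tr2), bn)
  idx <- which(st2$counts[1, ] > 0)
  expect_equal(((idx - 1) %% 3) + 1, 2)  # second rho bin
  # the top edge is right-closed
  tr3 <- manual_trajectory(3, 0.5)
  st3 <- build_histograms(list(tr3), bn)
  expect_equal(sum(st3$counts), 1)
  # out-of-range samples are excluded with a message
  tr4 <- manual_trajectory(c(0.5, 10), c(0.5, 0.5))
  expect_message(st4 <- build_histograms(list(tr4), bn), "outside")
  expect_equal(unname(st4$totals), 1)  # out-of-range sample not counted
  expect_equal(sum(st4$counts), 1)
})

test_that("histogram totals equal kept samples after broken exclusion", {
  grid <- build_window_grid(15, 5, c(-0.3, -0.7))
  st <- sampler_settings(n_samples = 1500, master_seed = 21)
  trajs <- run_protocol(hs_ref, grid, st, units300)
  trajs <- lapply(trajs, mark_broken, rule = function(s) s$roll > 10)
  state <- build_histograms(trajs, default_binning())
  kept <- vapply(trajs, function(t) sum(!t$broken), numeric(1))
  expect_equal(unname(state$totals), kept)
  expect_equal(length(state$totals), length(grid$windows))
})

test_that("single unbiased window collapses WHAM to the log-histogram", {
  withr::with_seed(6, {
    r <- stats::rnorm(5000, 0, 4)
    w <- stats::rnorm(5000, 0, 3)
  })
  tr <- manual_trajectory(r, w)
  bn <- default_binning(20, 2)
  state <- build_histograms(list(tr), bn)
  L <- wham_solve(state, units300, mask_floor = 5)
  n <- colSums(state$counts)
  expected <- -log(n / max(n))
  occ <- which(L$mask)
  expect_equal(L$deltaF[occ], expected[occ], tolerance = 1e-12)
  expect_equal(min(L$deltaF[L$mask]), 0)
})

test_that("two identical windows equal one window with pooled samples", {
  w <- bias_window(5, -0.5, 100)
  st1 <- sampler_settings(n_samples = 3000, master_seed = 41)
  trA <- sample_window(hs_ref, w, st1, units300)
  st2 <- sampler_settings(n_samples = 3000, master_seed = 43)
  trB <- sample_window(hs_ref, bias_window(5, -0.5, 100, window_id = "b"),
                       st2, units300)
  trB$window <- w
  pooled <- manual_trajectory(c(trA$samples$roll, trB$samples$roll),
                              c(trA$samples$twist_excess,
                                trB$samples$twist_excess), window = w)
  bn <- default_binning(30, 1)
  L2 <- wham_solve(build_histograms(list(trA, trB), bn), units300)
  L1 <- wham_solve(build_histograms(list(pooled), bn), units300)
  expect_equal(L2$deltaF[L2$mask], L1$deltaF[L1$mask], tolerance = 1e-6)
  expect_equal(L2$mask, L1$mask)
})

test_that("WHAM reconstructs random quadratic truth surfaces (oracle check)", {
  withr::with_seed(909, sets <- replicate(3, random_stiffness(),
                                          simplify = FALSE))
  for (i in seq_along(sets)) {
    hs <- sets[[i]]
    grid <- build_window_grid(24, 3, c(-0.3, -0.7), stiffness_k = 300)
    st <- sampler_settings(n_samples = 6000, master_seed = 600 + i)
    trajs <- run_protocol(hs, grid, st, units300)
    state <- build_histograms(trajs, default_binning(40, 1))
    L <- wham_solve(state, units300)
    ntot <- colSums(state$counts)
    occ <- which(L$mask & matrix(ntot >= 1000, nrow(L$deltaF)))
    nr <- length(L$binning$rho_centers)
    rho <- rep(L$binning$rho_centers,
               times = length(L$binning$omega_centers))[occ]
    om <- rep(L$binning$omega_centers, each = nr)[occ]
    dev <- L$deltaF[occ] - eval_harmonic(step_coords(0, rho, om), hs)
    dev <- dev - mean(dev)
    expect_gt(length(occ), 20)
    expect_lt(max(abs(dev)), 0.15)
  }
})

test_that("WHAM landscape is invariant to a constant shift of initial f", {
  grid <- build_window_grid(15, 5, -0.5)
  st <- sampler_settings(n_samples = 2000, master_seed = 77)
  trajs <- run_protocol(hs_ref, grid, st, units300)
  state <- build_histograms(trajs, default_binning(30, 1))
  L0 <- wham_solve(state, units300, tol = 1e-8)
  state$f <- rep(3.7, length(state$totals))
  L1 <- wham_solve(state, units300, tol = 1e-8)
  expect_equal(L0$deltaF[L0$mask], L1$deltaF[L1$mask], tolerance = 1e-6)
})

test_that("tightening the tolerance changes well-sampled bins by less than tol", {
  grid <- build_window_grid(15, 5, -0.5)
  st <- sampler_settings(n_samples = 2000, master_seed = 78)
  trajs <- run_protocol(hs_ref, grid, st, units300)
  state <- build_histograms(trajs, default_binning(30, 1))
  La <- wham_solve(state, units300, tol = 1e-5)
  Lb <- wham_solve(state, units300, tol = 1e-6)
  ntot <- colSums(state$counts)
  occ <- La$mask & Lb$mask & matrix(ntot >= 100, nrow(La$deltaF))
  expect_lt(max(abs(La$deltaF[occ] - Lb$deltaF[occ])), 1e-5)
  # residuals are nonincreasing over the recorded tail
  expect_true(all(diff(Lb$residual_tail) <= 1e-12))
})

test_that("disconnected histograms trigger a warning", {
  trA <- manual_trajectory(stats::runif(500, -10, -5),
                           stats::runif(500, -2, 2),
                           window = bias_window(-8, -0.1, 1000))
  trB <- manual_trajectory(stats::runif(500, 5, 10),
                           stats::runif(500, -2, 2),
                           window = bias_window(8, -0.1, 1000))
  state <- build_histograms(list(trA, trB), default_binning(20, 1))
  expect_warning(wham_solve(state, units300), "not connected")
})

test_that("profiles interpolate along slope lines with the right curvature", {
  co <- anharmonic_coefficients(a2 = 0.056, c2 = 0.097, g = 0.016)
  L <- exact_landscape(co, default_binning(40, 1))
  prof <- profile_from_landscape(L, slope = -0.6, rho_sign = "+")
  expect_s3_class(prof, "profile1d")
  # half the effective curvature: 0.03586 * rho^2 at rho = 10
  expect_equal(prof$deltaF[prof$rho == 10.5],
               0.5 * (0.056 + 2 * 0.016 * (-0.6) + 0.097 * 0.36) * 10.5^2,
               tolerance = 0.01)
  # quadratic curvature coefficient along the line: 0.03586 / deg^2
  fitc <- stats::lm(deltaF ~ I(rho^2) + rho, data = prof)
  expect_equal(unname(stats::coef(fitc)[["I(rho^2)"]]), 0.03586,
               tolerance = 0.01)
  # near the origin the profile returns to the reference level
  prof2 <- profile_from_landscape(L, slope = -0.1)
  expect_lt(abs(prof2$deltaF[prof2$rho == 0.5]), 0.05)
  # slope 0 equals the omega = 0 row (here: omega interpolated at 0)
  prof3 <- profile_from_landscape(L, slope = 0, rho_sign = "+")
  direct <- eval_anharmonic(step_coords(0, prof3$rho, 0), co)
  expect_equal(prof3$deltaF, direct, tolerance = 0.02)
  # a line with no unmasked cells errors
  Lm <- L
  Lm$mask[] <- FALSE
  Lm$mask[1, 1] <- TRUE
  expect_error(profile_from_landscape(Lm, slope = -0.6), "no unmasked")
})

test_that("landscape files round-trip bit-exactly", {
  grid <- build_window_grid(15, 5, -0.5)
  st <- sampler_settings(n_samples = 2000, master_seed = 55)
  trajs <- run_protocol(hs_ref, grid, st, units300)
  state <- build_histograms(trajs, default_binning(30, 1))
  L <- wham_solve(state, units300)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_landscape(L, tf)
  back <- read_landscape(tf)
  expect_identical(back$deltaF, L$deltaF)
  expect_identical(back$mask, L$mask)
  expect_identical(back$binning$rho_edges, L$binning$rho_edges)
  expect_identical(back$reference, L$reference)
})
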