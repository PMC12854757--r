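test_that("quadratic fit recovers its own basis exactly on exact data", {
  co <- anharmonic_coefficients(a2 = 0.056, c2 = 0.097, g = 0.016)
  L <- exact_landscape(co, default_binning(40, 1))
  fq <- fit_quadratic(L, cutoff = 3)
  expect_equal(fq$coefficients$a2, 0.056, tolerance = 1e-10)
  expect_equal(fq$coefficients$c2, 0.097, tolerance = 1e-10)
  expect_equal(fq$coefficients$g, 0.016, tolerance = 1e-10)
  expect_lt(fq$residual_rms, 1e-10)
  expect_gte(fq$n_bins_used, 3)
})

test_that("an empty fit region raises a fit error", {
  co <- anharmonic_coefficients(a2 = 0.056, c2 = 0.097, g = 0.016)
  L <- exact_landscape(co, default_binning(40, 1))
  expect_error(fit_quadratic(L, cutoff = min(L$deltaF[L$mask]) - 1),
               "no unmasked bins")
})

test_that("anharmonic stages recover exact coefficients with quadratic frozen at truth", {
  L <- exact_landscape(ddd, default_binning(40, 1), bound = 20)
  ff <- fit_anharmonic(L, ddd, cutoff = 7, stage = "full")
  for (t in c("a3", "c3", "b", "d", "a4", "c4", "h"))
    expect_equal(ff$coefficients[[t]], ddd[[t]], tolerance = 1e-8)
  expect_lt(ff$residual_rms, 1e-10)
  # the cubic-only stage on the same data absorbs quartics imperfectly but
  # still names the frozen block
  fc <- fit_anharmonic(L, ddd, cutoff = 7, stage = "cubic_only")
  expect_setequal(fc$frozen, c("a2", "c2", "g"))
  # freezing the cubic block in the full stage is also supported
  ff2 <- fit_anharmonic(L, ff, cutoff = 7, stage = "full",
                        refit_cubic = FALSE)
  expect_setequal(ff2$frozen, c("a2", "c2", "g", "a3", "c3", "b", "d"))
})

test_that("cubic coefficients vanish on a symmetric quadratic landscape", {
  # exact symmetric quadratic surface plus iid noise of known scale, so the
  # least-squares standard errors are valid and the odd basis is orthogonal
  # to the truth on the symmetric region
  co <- anharmonic_coefficients(a2 = 0.056, c2 = 0.097, g = 0.016)
  L <- exact_landscape(co, default_binning(40, 1))
  withr::with_seed(515, {
    noise <- matrix(stats::rnorm(length(L$deltaF), sd = 0.05),
                    nrow(L$deltaF))
  })
  L$deltaF <- L$deltaF + noise
  fq <- fit_quadratic(L, cutoff = 3)
  fc <- fit_anharmonic(L, fq, cutoff = 7, stage = "cubic_only")
  for (t in c("a3", "c3", "b", "d"))
    expect_lt(abs(fc$coefficients[[t]]), 3 * fc$se[[t]])
})

test_that("non-positive-definite fitted quadratic blocks raise a warning", {
  # hand-built saddle landscape: positive curvature in roll, negative in
  # twist, so the fitted quadratic block cannot be positive definite
  bn <- default_binning(10, 1)
  nr <- length(bn$rho_centers); nw <- length(bn$omega_centers)
  rho <- rep(bn$rho_centers, times = nw)
  om <- rep(bn$omega_centers, each = nr)
  L <- structure(list(
    binning = bn, deltaF = matrix((rho^2 - om^2) / 100, nr, nw),
    mask = matrix(TRUE, nr, nw), reference = c(rho = 0.5, omega = 0.5),
    f = NULL, iterations = 0L, converged = TRUE, residual = 0,
    residual_tail = numeric(0), provenance = "synthetic saddle"),
    class = "landscape_grid")
  expect_warning(fit_quadratic(L, cutoff = 3), "not positive definite")
})

test_that("flattening detection finds the analytic inflection of a cubic profile", {
  rho <- seq(0, 60, by = 0.5)
  prof <- data.frame(rho = rho, deltaF = 0.03 * rho^2 - 2e-4 * rho^3)
  res <- detect_flattening(prof, curvature_threshold = 0,
                           smooth_halfwidth = 5)
  # curvature 0.06 - 0.0012 rho crosses zero at rho = 50
  expect_equal(nrow(res$candidates), 1)
  expect_equal(res$candidates$rho_start, 50, tolerance = 0.04)
  # a pure quadratic profile yields no candidates at threshold 0
  prof2 <- data.frame(rho = rho, deltaF = 0.03 * rho^2)
  res2 <- detect_flattening(prof2, 0, 5)
  expect_equal(nrow(res2$candidates), 0)
  # a threshold above the max curvature flags one run spanning the profile
  res3 <- detect_flattening(prof2, 1, 5)
  expect_equal(nrow(res3$candidates), 1)
  expect_equal(res3$candidates$rho,
               (res3$candidates$rho_start + res3$candidates$rho_end) / 2,
               tolerance = 0.02)
  expect_error(detect_flattening(prof[1:8, ], 0, 5), "too short")
})

test_that("kink classification follows the TB/PB taxonomy", {
  calls <- classify_kink(step_coords(
    tilt = 0,
    roll = c(30, -40, 5, 60, -50, 25, -25),
    twist_excess = c(-5, -2, 0, -10, -3, 3, -10)))
  expect_equal(as.character(calls$kind),
               c("TB", "PB", "none", "TB", "PB", "none", "none"))
  # classification is scale-free in deltaF: same calls whatever energy is
  # attached
  calls2 <- classify_kink(step_coords(0, c(30, -40), c(-5, -2)),
                          deltaF_at_site = c(21, 99))
  expect_equal(as.character(calls2$kind), c("TB", "PB"))
  # thresholds travel with the call
  expect_s3_class(attr(calls, "settings"), "kink_settings")
})

test_that("asymmetry metric matches direct surface evaluation", {
  co <- anharmonic_coefficients(a2 = 0.056, c2 = 0.097, g = 0.016)
  Lq <- exact_landscape(co, default_binning(40, 1))
  sym <- asymmetry_metric(Lq, slope_neg = -0.6, slope_pos = -0.6,
                          rho_probe = 15)
  expect_equal(sym$difference, 0, tolerance = 0.02)
  # on the asymmetric truth surface the metric equals the closed form
  La <- exact_landscape(ddd, default_binning(40, 1), bound = 25,
                        exclude = breakage_rule_radial(ddd))
  m <- asymmetry_metric(La, slope_neg = -0.1, slope_pos = -0.6,
                        rho_probe = 15)
  direct_pos <- eval_anharmonic(step_coords(0, 15, -9), ddd)
  direct_neg <- eval_anharmonic(step_coords(0, -15, 1.5), ddd)
  expect_equal(m$difference, direct_pos - direct_neg, tolerance = 0.05)
  expect_gt(m$difference, 0)  # negative roll is cheaper on this surface
  expect_error(asymmetry_metric(La, rho_probe = 80), "masked or outside")
})

test_that("fit tables serialize with printed scale factors", {
  L <- exact_landscape(ddd, default_binning(40, 1), bound = 20)
  fits <- stepwise_fit(L)
  tf <- withr::local_tempfile(fileext = ".txt")
  lines <- write_fit_table(fits, tf)
  expect_true(file.exists(tf))
  expect_true(any(grepl("quadratic.k2", lines)))
  expect_true(any(grepl("full.k4", lines)))
})
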