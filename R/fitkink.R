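# Design matrix columns for the polynomial surface. Every model term carries
# the global 1/2 (and the coupling term its factor 2), so the fitted
# coefficients are directly the a2/c2/g/... of the energy convention.
surface_basis <- function(rho, omega, terms) {
  cols <- list(
    a2 = 0.5 * rho^2, c2 = 0.5 * omega^2, g = rho * omega,
    a3 = 0.5 * rho^3, c3 = 0.5 * omega^3,
    b = 0.5 * rho^2 * omega, d = 0.5 * rho * omega^2,
    a4 = 0.5 * rho^4, c4 = 0.5 * omega^4, h = 0.5 * rho^2 * omega^2
  )
  do.call(cbind, cols[terms])
}

# Unmasked bins of a landscape with deltaF <= cutoff, as vectors.
fit_region <- function(grid, cutoff) {
  sel <- which(grid$mask & grid$deltaF <= cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    stop(sprintf("no unmasked bins with deltaF <= %g kBT", cutoff))
  list(rho = grid$binning$rho_centers[sel[, 1]],
       omega = grid$binning$omega_centers[sel[, 2]],
       deltaF = grid$deltaF[sel])
}

ls_fit <- function(X, y, term_names) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop(sprintf("fit region is underdetermined for basis {%s}",
                 paste(term_names, collapse = ", ")))
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  dof <- max(length(y) - ncol(X), 1L)
  sigma2 <- sum(res^2) / dof
  XtX_inv <- chol2inv(qr.R(qrX))
  list(coef = as.numeric(beta), se = sqrt(sigma2 * diag(XtX_inv)),
       residual_rms = sqrt(mean(res^2)), n = length(y))
}

#' Fit the quadratic block of the surface to a landscape
#'
#' Stage 1 of the stepwise surface fit: unweighted linear least squares of
#' \eqn{\Delta F} on the quadratic basis \eqn{\{\rho^2, \Omega^2,
#' \rho\Omega\}} (with the global 1/2 and the 2G coupling convention), over
#' unmasked bins with \eqn{\Delta F \le} `cutoff`. The harmonic model
#' describes these surfaces well only up to about 3 \eqn{k_B T}, which is
#' the default cutoff.
#'
#' @param grid a `landscape_grid`.
#' @param cutoff free-energy cutoff in \eqn{k_B T} bounding the fit region.
#' @param intercept include a free constant absorbing the reference shift of
#'   the landscape (default `TRUE`; the WHAM reference bin need not sit
#'   exactly at the origin of the surface).
#' @return an object of class `fit_report` with fields `coefficients` (an
#'   [anharmonic_coefficients()] with zero cubic/quartic blocks), `stage`
#'   (`"quadratic"`), `region_cutoff`, `n_bins_used`, `residual_rms`, `se`
#'   (named standard errors), `frozen` (empty).
#' @export
fit_quadratic <- function(grid, cutoff = 3, intercept = TRUE) {
  stopifnot(inherits(grid, "landscape_grid"))
  reg <- fit_region(grid, cutoff)
  terms <- c("a2", "c2", "g")
  X <- surface_basis(reg$rho, reg$omega, terms)
  if (intercept) X <- cbind(X, intercept = 1)
  if (nrow(X) < ncol(X))
    stop("fewer bins under the cutoff than free coefficients")
  fit <- ls_fit(X, reg$deltaF, terms)
  names(fit$coef) <- colnames(X)
  names(fit$se) <- colnames(X)
  co <- fit$coef
  if (co[["a2"]] <= 0 || co[["c2"]] <= 0 ||
      co[["a2"]] * co[["c2"]] <= co[["g"]]^2) {
    warning("fitted quadratic block is not positive definite")
    coeffs <- list(a2 = co[["a2"]], c2 = co[["c2"]], g = co[["g"]],
                   a3 = 0, c3 = 0, b = 0, d = 0, a4 = 0, c4 = 0, h = 0,
                   fit_cutoff_quadratic = cutoff, fit_cutoff_full = cutoff)
    class(coeffs) <- "anharmonic_coefficients"
  } else {
    coeffs <- anharmonic_coefficients(
      a2 = co[["a2"]], c2 = co[["c2"]], g = co[["g"]],
      fit_cutoff_quadratic = cutoff, fit_cutoff_full = cutoff)
  }
  new_fit_report(coeffs, "quadratic", cutoff, fit, frozen = character(0))
}

#' Fit cubic (and quartic) terms with the quadratic block frozen
#'
#' Stages 2 and 3 of the stepwise fit: linear least squares of the residual
#' \eqn{\Delta F - } (frozen quadratic part) on the cubic basis
#' \eqn{\{\rho^3, \Omega^3, \rho^2\Omega, \rho\Omega^2\}} (`stage =
#' "cubic_only"`) or that basis plus \eqn{\{\rho^4, \Omega^4,
#' \rho^2\Omega^2\}} (`stage = "full"`), over unmasked bins with
#' \eqn{\Delta F \le} `cutoff`. The mixed quartics \eqn{\rho^3\Omega} and
#' \eqn{\rho\Omega^3} are never included: they do not significantly improve
#' these fits. In the full stage the cubic block is refit jointly with the
#' quartic by default; set `refit_cubic = FALSE` to freeze it at supplied
#' values instead (both successive-fit conventions are in use).
#'
#' @param grid a `landscape_grid`.
#' @param frozen_quadratic an [anharmonic_coefficients()] (or `fit_report`)
#'   whose quadratic block (and, if `refit_cubic = FALSE`, cubic block) is
#'   held fixed.
#' @param cutoff fit-region cutoff in \eqn{k_B T} (default 7).
#' @param stage `"cubic_only"` or `"full"`.
#' @param refit_cubic full stage only: refit the cubic block jointly with
#'   the quartic (default) or keep it frozen.
#' @param intercept include a free constant (see [fit_quadratic()]).
#' @return a `fit_report`; `frozen` names the coefficients held fixed.
#' @export
fit_anharmonic <- function(grid, frozen_quadratic, cutoff = 7,
                           stage = c("full", "cubic_only"),
                           refit_cubic = TRUE, intercept = TRUE) {
  stopifnot(inherits(grid, "landscape_grid"))
  stage <- match.arg(stage)
  if (inherits(frozen_quadratic, "fit_report"))
    frozen_quadratic <- frozen_quadratic$coefficients
  stopifnot(inherits(frozen_quadratic, "anharmonic_coefficients"))
  fq <- frozen_quadratic
  reg <- fit_region(grid, cutoff)

  frozen_terms <- c("a2", "c2", "g")
  frozen_vals <- c(fq$a2, fq$c2, fq$g)
  free_terms <- c("a3", "c3", "b", "d")
  if (stage == "full") {
    if (refit_cubic) {
      free_terms <- c(free_terms, "a4", "c4", "h")
    } else {
      frozen_terms <- c(frozen_terms, free_terms)
      frozen_vals <- c(frozen_vals, fq$a3, fq$c3, fq$b, fq$d)
      free_terms <- c("a4", "c4", "h")
    }
  }
  Xfrozen <- surface_basis(reg$rho, reg$omega, frozen_terms)
  y <- reg$deltaF - as.vector(Xfrozen %*% frozen_vals)
  X <- surface_basis(reg$rho, reg$omega, free_terms)
  if (intercept) X <- cbind(X, intercept = 1)
  if (nrow(X) < ncol(X))
    stop("fewer bins under the cutoff than free coefficients")
  fit <- ls_fit(X, y, free_terms)
  names(fit$coef) <- colnames(X)
  names(fit$se) <- colnames(X)

  all_terms <- c("a2", "c2", "g", "a3", "c3", "b", "d", "a4", "c4", "h")
  vals <- stats::setNames(rep(0, length(all_terms)), all_terms)
  vals[frozen_terms] <- frozen_vals
  vals[free_terms] <- fit$coef[free_terms]
  coeffs <- list(a2 = vals[["a2"]], c2 = vals[["c2"]], g = vals[["g"]],
                 a3 = vals[["a3"]], c3 = vals[["c3"]], b = vals[["b"]],
                 d = vals[["d"]], a4 = vals[["a4"]], c4 = vals[["c4"]],
                 h = vals[["h"]],
                 fit_cutoff_quadratic = fq$fit_cutoff_quadratic,
                 fit_cutoff_full = cutoff)
  class(coeffs) <- "anharmonic_coefficients"
  new_fit_report(coeffs, stage, cutoff, fit, frozen = frozen_terms)
}

new_fit_report <- function(coeffs, stage, cutoff, fit, frozen) {
  structure(
    list(coefficients = coeffs, stage = stage, region_cutoff = cutoff,
         n_bins_used = fit$n, residual_rms = fit$residual_rms,
         se = fit$se, frozen = frozen),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "fit_report [%s]: %d bins with deltaF <= %g kBT, residual rms %.4f kBT\n",
    x$stage, x$n_bins_used, x$region_cutoff, x$residual_rms))
  if (length(x$frozen))
    cat("  frozen:", paste(x$frozen, collapse = ", "), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Serialize a stepwise fit as a coefficient-table text report
#'
#' Writes the successive-stage coefficients as a conventional table with
#' rows quadratic/cubic/quartic and the printed scale factors (1e-2, 1e-4,
#' 1e-5) re-applied for display.
#'
#' @param reports a list of `fit_report` objects (typically quadratic,
#'   cubic_only, full).
#' @param path output path; omit to return the lines invisibly.
#' @return the formatted lines, invisibly.
#' @export
write_fit_table <- function(reports, path = NULL) {
  if (inherits(reports, "fit_report")) reports <- list(reports)
  lines <- c("# stepwise anharmonic surface fit",
             "# scales: quadratic x 1e-2, cubic x 1e-4, quartic x 1e-5",
             sprintf("%-12s %8s %8s %8s %8s %8s %8s %12s %8s",
                     "stage", "A_rho", "C", "G", "B", "D", "H",
                     "rms_kBT", "n_bins"))
  for (r in reports) {
    co <- r$coefficients
    fmtrow <- function(stage, a, cc, g, b, d, h)
      sprintf("%-12s %8.3g %8.3g %8s %8s %8s %8s %12.4g %8d",
              stage, a, cc,
              if (is.na(g)) "-" else sprintf("%.3g", g),
              if (is.na(b)) "-" else sprintf("%.3g", b),
              if (is.na(d)) "-" else sprintf("%.3g", d),
              if (is.na(h)) "-" else sprintf("%.3g", h),
              r$residual_rms, r$n_bins_used)
    lines <- c(lines,
      fmtrow(paste0(r$stage, ".k2"), 1e2 * co$a2, 1e2 * co$c2, 1e2 * co$g,
             NA, NA, NA),
      if (r$stage != "quadratic")
        fmtrow(paste0(r$stage, ".k3"), 1e4 * co$a3, 1e4 * co$c3, NA,
               1e4 * co$b, 1e4 * co$d, NA),
      if (r$stage == "full")
        fmtrow(paste0(r$stage, ".k4"), 1e5 * co$a4, 1e5 * co$c4, NA,
               NA, NA, 1e5 * co$h))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Detect flattening regions on a 1D profile
#'
#' Estimates the local curvature \eqn{d^2\Delta F/d\rho^2} along a profile by
#' local quadratic smoothing over a window of `2 * smooth_halfwidth + 1`
#' points, and reports contiguous runs where the curvature falls below
#' `curvature_threshold`. Flattening regions are tentative kink candidates:
#' they are reported with the full curvature trace for inspection and are
#' never auto-promoted to kink calls. A monotone increase of \eqn{\Delta F}
#' is not required.
#'
#' @param profile a `profile1d` (or data.frame with `rho`, `deltaF`).
#' @param curvature_threshold curvature threshold in \eqn{k_B T} per squared
#'   degree.
#' @param smooth_halfwidth half-width of the smoothing window in points
#'   (default 5).
#' @return a list with `candidates` (data.frame: `rho_start`, `rho`,
#'   `rho_end`, `deltaF`, `min_curvature` — one row per run, `rho` the run
#'   midpoint) and `trace` (data.frame: `rho`, `deltaF`, `curvature`).
#' @export
detect_flattening <- function(profile, curvature_threshold = 0,
                              smooth_halfwidth = 5) {
  if (!is.data.frame(profile) || !all(c("rho", "deltaF") %in% names(profile)))
    stop("profile must have columns rho and deltaF")
  ok <- is.finite(profile$deltaF)
  rho <- profile$rho[ok]
  dF <- profile$deltaF[ok]
  hw <- as.integer(smooth_halfwidth)
  if (hw < 1L) stop("smooth_halfwidth must be >= 1")
  n <- length(rho)
  if (n < 2L * hw + 1L)
    stop(sprintf("profile too short: %d defined points, need >= %d",
                 n, 2L * hw + 1L))
  curv <- rep(NA_real_, n)
  for (i in (hw + 1L):(n - hw)) {
    idx <- (i - hw):(i + hw)
    x <- rho[idx] - rho[i]
    co <- stats::lm.fit(cbind(1, x, x^2), dF[idx])$coefficients
    curv[i] <- 2 * co[3L]
  }
  flat <- !is.na(curv) & curv < curvature_threshold
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  cand <- data.frame(rho_start = numeric(0), rho = numeric(0),
                     rho_end = numeric(0), deltaF = numeric(0),
                     min_curvature = numeric(0))
  for (k in sel) {
    i0 <- starts[k]; i1 <- ends[k]
    mid <- (rho[i0] + rho[i1]) / 2
    imid <- i0 + which.min(abs(rho[i0:i1] - mid)) - 1L
    cand <- rbind(cand, data.frame(
      rho_start = rho[i0], rho = rho[imid], rho_end = rho[i1],
      deltaF = dF[imid], min_curvature = min(curv[i0:i1])))
  }
  list(candidates = cand,
       trace = data.frame(rho = rho, deltaF = dF, curvature = curv))
}

#' Kink classification thresholds
#'
#' Thresholds separating twist-bend (TB) from pure-bend (PB) kinks. TB kinks
#' combine large positive roll with undertwisting (negative excess twist), as
#' seen at protein-induced kinks such as IHF sites; PB kinks combine large
#' negative roll with little or no excess twist, as seen in minicircle
#' simulations and torsionally constrained DNA. The defaults are
#' conventions, not measured values, and are recorded in every call.
#'
#' @param roll_min_tb minimum roll for a TB call (degrees).
#' @param roll_min_pb minimum |roll| for a PB call (degrees; roll must be
#'   negative).
#' @param twist_min_tb minimum undertwist magnitude for TB (degrees;
#'   excess twist must be <= -twist_min_tb).
#' @param twist_tol_pb maximum |excess twist| for PB (degrees).
#' @return a list of class `kink_settings`.
#' @export
kink_settings <- function(roll_min_tb = 20, roll_min_pb = 20,
                          twist_min_tb = 2, twist_tol_pb = 5) {
  v <- c(roll_min_tb, roll_min_pb, twist_min_tb, twist_tol_pb)
  if (!all(is.finite(v)) || any(v < 0)) stop("thresholds must be >= 0")
  structure(list(roll_min_tb = roll_min_tb, roll_min_pb = roll_min_pb,
                 twist_min_tb = twist_min_tb, twist_tol_pb = twist_tol_pb),
            class = "kink_settings")
}

#' Classify a deformation as twist-bend, pure-bend or neither
#'
#' Applies the TB/PB taxonomy to step coordinates: TB iff roll >=
#' `roll_min_tb` and excess twist <= `-twist_min_tb`; PB iff roll <=
#' `-roll_min_pb` and |excess twist| <= `twist_tol_pb`; otherwise `none`.
#' The call depends only on the coordinates, never on \eqn{\Delta F}.
#'
#' @param coords step coordinates (one or more rows).
#' @param settings a [kink_settings()].
#' @param deltaF_at_site optional free energies (\eqn{k_B T}) to carry along.
#' @return a data.frame of class `kink_call` with columns `roll`,
#'   `twist_excess`, `kind` (factor TB/PB/none), `deltaF_at_site`; the
#'   thresholds used are attached as attribute `settings`.
#' @export
classify_kink <- function(coords, settings = kink_settings(),
                          deltaF_at_site = NA_real_) {
  coords <- as_step_coords(coords)
  stopifnot(inherits(settings, "kink_settings"))
  r <- coords$roll
  w <- coords$twist_excess
  kind <- rep("none", length(r))
  kind[r >= settings$roll_min_tb & w <= -settings$twist_min_tb] <- "TB"
  kind[r <= -settings$roll_min_pb & abs(w) <= settings$twist_tol_pb] <- "PB"
  out <- data.frame(
    roll = r, twist_excess = w,
    kind = factor(kind, levels = c("TB", "PB", "none")),
    deltaF_at_site = rep_len(deltaF_at_site, length(r)))
  attr(out, "settings") <- settings
  class(out) <- c("kink_call", "data.frame")
  out
}

#' Positive/negative-roll asymmetry of a landscape
#'
#' Reports \eqn{\Delta F} at two probe points on the landscape — along
#' \eqn{\Omega =} `slope_pos` \eqn{\cdot\rho} at \eqn{\rho = +}`rho_probe`
#' and along \eqn{\Omega =} `slope_neg` \eqn{\cdot\rho} at
#' \eqn{\rho = -}`rho_probe` — and their difference. On these surfaces free
#' energies are generically smaller at negative roll than at positive roll,
#' the signature of the cubic/quartic asymmetry.
#'
#' @param grid a `landscape_grid`.
#' @param slope_neg,slope_pos line slopes for the negative and positive roll
#'   branches (the conventional guide lines are -0.1 and -0.6).
#' @param rho_probe probe |roll| in degrees.
#' @return a list with `deltaF_pos`, `deltaF_neg` and `difference`
#'   (pos - neg), in \eqn{k_B T}.
#' @export
asymmetry_metric <- function(grid, slope_neg = -0.1, slope_pos = -0.6,
                             rho_probe = 15) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (!is.finite(rho_probe) || rho_probe <= 0)
    stop("rho_probe must be positive")
  dpos <- interp_landscape(grid, rho_probe, slope_pos * rho_probe)
  dneg <- interp_landscape(grid, -rho_probe, slope_neg * (-rho_probe))
  if (is.na(dpos) || is.na(dneg))
    stop("probe point is masked or outside the landscape")
  list(deltaF_pos = dpos, deltaF_neg = dneg, difference = dpos - dneg)
}
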