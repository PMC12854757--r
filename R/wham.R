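#' Two-dimensional histogram binning
#'
#' Bin-edge definition for the (roll, excess twist) plane. Bins are
#' half-open `[left, right)` with the topmost edge right-closed, so a sample
#' exactly on an interior edge belongs to the right-hand bin.
#'
#' @param rho_edges,omega_edges strictly increasing numeric edge vectors in
#'   degrees, at least 3 values (2 bins) each.
#' @return an object of class `binning2d` with derived bin centers.
#' @export
binning2d <- function(rho_edges, omega_edges) {
  chk <- function(e, nm) {
    if (!is.numeric(e) || length(e) < 3L || any(!is.finite(e)) ||
        any(diff(e) <= 0))
      stop(sprintf("`%s` must be >= 3 strictly increasing finite values", nm))
    as.numeric(e)
  }
  rho_edges <- chk(rho_edges, "rho_edges")
  omega_edges <- chk(omega_edges, "omega_edges")
  structure(
    list(rho_edges = rho_edges, omega_edges = omega_edges,
         rho_centers = (rho_edges[-1] + rho_edges[-length(rho_edges)]) / 2,
         omega_centers =
           (omega_edges[-1] + omega_edges[-length(omega_edges)]) / 2),
    class = "binning2d"
  )
}

#' Default binning: 1 degree by 1 degree over [-95, 95]^2
#'
#' Covers the standard bias range (roll targets up to 1.6 rad = 91.7 deg)
#' with one-degree bins.
#'
#' @param half_range half-width of the square grid in degrees.
#' @param width bin width in degrees.
#' @return a [binning2d()].
#' @export
default_binning <- function(half_range = 95, width = 1) {
  e <- seq(-half_range, half_range, by = width)
  binning2d(e, e)
}

# Flat bin index (1-based) for coordinate pairs; NA outside the range.
# Half-open [left, right) bins, top edge closed.
bin_index2d <- function(binning, rho, omega) {
  nr <- length(binning$rho_centers)
  nw <- length(binning$omega_centers)
  ir <- findInterval(rho, binning$rho_edges, left.open = FALSE,
                     rightmost.closed = TRUE)
  iw <- findInterval(omega, binning$omega_edges, left.open = FALSE,
                     rightmost.closed = TRUE)
  ir[ir < 1L | ir > nr] <- NA_integer_
  iw[iw < 1L | iw > nw] <- NA_integer_
  ifelse(is.na(ir) | is.na(iw), NA_integer_, (iw - 1L) * nr + ir)
}

#' Build per-window histograms for WHAM
#'
#' Histograms each trajectory on the common binning, excluding samples
#' flagged broken and (with a message) samples outside the binning range.
#'
#' @param trajs a list of `window_trajectory` objects (e.g. from
#'   [run_protocol()]).
#' @param binning a [binning2d()].
#' @return an object of class `wham_state`: `counts` (windows x bins
#'   matrix), `totals` (kept samples per window), `windows` (list of
#'   [bias_window()]), `binning`, plus iteration fields filled by
#'   [wham_solve()] (`f`, `iterations`, `converged`, `residual`).
#' @export
build_histograms <- function(trajs, binning) {
  stopifnot(inherits(binning, "binning2d"))
  if (length(trajs) == 0L) stop("no trajectories supplied")
  nbin <- length(binning$rho_centers) * length(binning$omega_centers)
  counts <- matrix(0, nrow = length(trajs), ncol = nbin)
  windows <- vector("list", length(trajs))
  dropped_out_of_range <- 0L
  for (j in seq_along(trajs)) {
    traj <- trajs[[j]]
    stopifnot(inherits(traj, "window_trajectory"))
    windows[j] <- list(traj$window)  # keep NULL (unbiased) windows in place
    keep <- !traj$broken
    idx <- bin_index2d(binning, traj$samples$roll[keep],
                       traj$samples$twist_excess[keep])
    dropped_out_of_range <- dropped_out_of_range + sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    if (length(idx))
      counts[j, ] <- tabulate(idx, nbins = nbin)
  }
  totals <- rowSums(counts)
  if (sum(totals) == 0)
    stop("no usable samples: all broken, or all outside the binning range")
  if (dropped_out_of_range > 0L)
    message(sprintf("build_histograms: %d samples outside binning range excluded",
                    dropped_out_of_range))
  structure(
    list(counts = counts, totals = totals, windows = windows,
         binning = binning, f = rep(0, length(trajs)),
         iterations = 0L, converged = NA, residual = NA_real_),
    class = "wham_state"
  )
}

#' @export
print.wham_state <- function(x, ...) {
  cat(sprintf(
    "wham_state: %d windows, %d x %d bins, %g kept samples%s\n",
    nrow(x$counts), length(x$binning$rho_centers),
    length(x$binning$omega_centers), sum(x$totals),
    if (isTRUE(x$converged))
      sprintf("; converged in %d iterations (residual %.2e kBT)",
              x$iterations, x$residual)
    else ""))
  invisible(x)
}

# Bias energies (kBT) of each window at a set of bin centers.
bias_matrix <- function(windows, rho, omega, units) {
  V <- matrix(0, nrow = length(windows), ncol = length(rho))
  for (j in seq_along(windows)) {
    w <- windows[[j]]
    if (is.null(w)) next  # unbiased window: V = 0
    k_deg <- bias_stiffness_deg(w$stiffness_k, units)
    V[j, ] <- 0.5 * k_deg *
      ((rho - w$rho_bar)^2 + (omega - omega_bar(w))^2)
  }
  V
}

#' Solve the WHAM equations on 2D histograms
#'
#' Self-consistent iteration of the weighted histogram analysis method:
#' \deqn{P(b) = \frac{\sum_i n_i(b)}{\sum_j N_j \exp(\beta f_j - \beta
#' V_j(b))}, \qquad \beta f_j = -\ln \sum_b P(b) e^{-\beta V_j(b)}}
#' until the largest change in any window free energy \eqn{f_j} falls below
#' `tol`, then the free-energy surface \eqn{\Delta F(b) = -k_BT \ln
#' P(b)/P(b_{\min})} referenced to the minimum bin. The bias is evaluated at
#' bin centers. Bins whose total count across windows falls below
#' `mask_floor` are masked.
#'
#' @param state a `wham_state` from [build_histograms()].
#' @param units a [unit_system()].
#' @param tol convergence tolerance on the window free energies, \eqn{k_B T}.
#' @param max_iter iteration cap; non-convergence returns a result with
#'   `converged = FALSE` and a warning.
#' @param mask_floor minimum total count for a bin to be reported (guards
#'   the logarithm of small counts).
#' @return an object of class `landscape_grid`: `binning`, `deltaF` (matrix,
#'   rho by omega, \eqn{k_B T}, `NA` where masked), `mask` (logical matrix,
#'   `TRUE` = valid), `reference` (rho/omega centers of the minimum bin),
#'   `f` (converged window free energies), `iterations`, `converged`,
#'   `residual`, `provenance`.
#' @export
wham_solve <- function(state, units = unit_system(), tol = 1e-6,
                       max_iter = 1e5, mask_floor = 5) {
  stopifnot(inherits(state, "wham_state"), inherits(units, "unit_system"))
  binning <- state$binning
  nr <- length(binning$rho_centers)
  nw <- length(binning$omega_centers)
  n_tot <- colSums(state$counts)
  occupied <- which(n_tot > 0)
  if (length(occupied) == 0L) stop("empty histograms: no occupied bins")
  check_overlap(state, occupied)

  centers_r <- rep(binning$rho_centers, times = nw)[occupied]
  centers_w <- rep(binning$omega_centers, each = nr)[occupied]
  V <- bias_matrix(state$windows, centers_r, centers_w, units)
  expnegV <- exp(-V)                       # windows x occupied bins
  N <- state$totals
  num <- n_tot[occupied]

  f <- state$f
  if (length(f) != length(N)) f <- rep(0, length(N))
  iter <- 0L
  resid <- Inf
  resid_tail <- numeric(0)                 # last 10 residuals, for diagnostics
  repeat {
    iter <- iter + 1L
    denom <- as.vector(crossprod(expnegV, N * exp(f)))
    P <- num / denom
    fnew <- -log(as.vector(expnegV %*% P))
    fnew <- fnew - fnew[1L]                # gauge: f_1 = 0
    resid <- max(abs(fnew - f))
    f <- fnew
    resid_tail <- c(utils::tail(resid_tail, 9L), resid)
    if (resid < tol || iter >= max_iter) break
  }
  converged <- resid < tol
  if (!converged)
    warning(sprintf(
      "WHAM did not converge in %d iterations (residual %.3e kBT > tol %.1e)",
      iter, resid, tol))

  denom <- as.vector(crossprod(expnegV, N * exp(f)))
  P <- num / denom
  P <- P / sum(P)                          # normalize over unmasked support

  keep <- n_tot[occupied] >= mask_floor
  if (!any(keep)) stop("all occupied bins fall below the mask floor")
  deltaF <- matrix(NA_real_, nr, nw)
  mask <- matrix(FALSE, nr, nw)
  vals <- -log(P)
  vals[!keep] <- NA_real_
  deltaF[occupied] <- vals
  mask[occupied] <- keep

  # reference: argmin bin; ties broken by smallest (|rho|, |omega|)
  cand <- which(mask & deltaF <= min(deltaF[mask]) + 1e-12, arr.ind = TRUE)
  ord <- order(abs(binning$rho_centers[cand[, 1]]),
               abs(binning$omega_centers[cand[, 2]]))
  ref <- cand[ord[1L], , drop = TRUE]
  deltaF <- deltaF - deltaF[ref[1L], ref[2L]]

  structure(
    list(binning = binning, deltaF = deltaF, mask = mask,
         reference = c(rho = binning$rho_centers[ref[1L]],
                       omega = binning$omega_centers[ref[2L]]),
         f = f, iterations = iter, converged = converged, residual = resid,
         residual_tail = resid_tail,
         provenance = sprintf("wham tol=%g max_iter=%g mask_floor=%g T=%gK",
                              tol, max_iter, mask_floor, units$temperature)),
    class = "landscape_grid"
  )
}

# Warn when the occupied bins do not form a single connected component
# across windows (poor histogram overlap makes WHAM ill-conditioned).
check_overlap <- function(state, occupied) {
  occ <- state$counts[, occupied, drop = FALSE] > 0
  occ <- occ[rowSums(occ) > 0, , drop = FALSE]  # fully-excluded windows
  n_win <- nrow(occ)
  if (n_win <= 1L) return(invisible(TRUE))
  comp <- seq_len(n_win)
  repeat {
    changed <- FALSE
    for (a in seq_len(n_win - 1L)) for (b in seq((a + 1L), n_win)) {
      if (comp[a] != comp[b] && any(occ[a, ] & occ[b, ])) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1L)
    warning(sprintf(
      "histograms are not connected: %d disjoint window components; WHAM free energies are only determined within components",
      length(unique(comp))))
  invisible(TRUE)
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "landscape_grid: %d x %d bins, %d valid; max deltaF %.2f kBT; reference (%.2f, %.2f) deg%s\n",
    nrow(x$deltaF), ncol(x$deltaF), sum(x$mask),
    max(x$deltaF[x$mask]), x$reference[["rho"]], x$reference[["omega"]],
    if (isTRUE(x$converged)) "" else " [WHAM not converged]"))
  invisible(x)
}

# Bilinear interpolation of deltaF at arbitrary (rho, omega) points.
# Returns NA when any of the four surrounding cell centers is masked or
# the point is outside the center lattice.
interp_landscape <- function(grid, rho, omega) {
  rc <- grid$binning$rho_centers
  wc <- grid$binning$omega_centers
  out <- rep(NA_real_, length(rho))
  ir <- findInterval(rho, rc)
  iw <- findInterval(omega, wc)
  ok <- ir >= 1L & ir < length(rc) & iw >= 1L & iw < length(wc)
  # points exactly at the top centers
  at_top_r <- rho == rc[length(rc)]
  at_top_w <- omega == wc[length(wc)]
  ir[at_top_r] <- length(rc) - 1L
  iw[at_top_w] <- length(wc) - 1L
  ok <- ok | (at_top_r & iw >= 1L & iw < length(wc)) |
        (at_top_w & ir >= 1L & ir < length(rc)) | (at_top_r & at_top_w)
  for (i in which(ok)) {
    i1 <- ir[i]; j1 <- iw[i]
    if (!all(grid$mask[i1:(i1 + 1L), j1:(j1 + 1L)])) next
    tx <- (rho[i] - rc[i1]) / (rc[i1 + 1L] - rc[i1])
    ty <- (omega[i] - wc[j1]) / (wc[j1 + 1L] - wc[j1])
    z <- grid$deltaF
    out[i] <- (1 - tx) * (1 - ty) * z[i1, j1] +
              tx * (1 - ty) * z[i1 + 1L, j1] +
              (1 - tx) * ty * z[i1, j1 + 1L] +
              tx * ty * z[i1 + 1L, j1 + 1L]
  }
  out
}

#' Extract a 1D free-energy profile along a roll/twist line
#'
#' Interpolates \eqn{\Delta F} bilinearly along the line
#' \eqn{\Omega = s\,\rho} for roll values of the requested sign, sampled at
#' bin-center resolution. Masked cells propagate as gaps (`NA`).
#'
#' @param grid a `landscape_grid`.
#' @param slope dimensionless line slope \eqn{s}.
#' @param rho_sign `"+"` for the positive-roll branch, `"-"` for negative,
#'   `"both"` for the full line.
#' @return an object of class `profile1d`: data.frame with columns `rho`,
#'   `deltaF`, plus attributes `slope` and `gaps` (logical).
#' @export
profile_from_landscape <- function(grid, slope, rho_sign = c("both", "+", "-")) {
  stopifnot(inherits(grid, "landscape_grid"))
  rho_sign <- match.arg(rho_sign)
  rho <- grid$binning$rho_centers
  rho <- switch(rho_sign, "+" = rho[rho >= 0], "-" = rho[rho <= 0], rho)
  dF <- interp_landscape(grid, rho, slope * rho)
  if (all(is.na(dF)))
    stop("no unmasked cells on the requested profile line")
  out <- data.frame(rho = rho, deltaF = dF)
  attr(out, "slope") <- slope
  attr(out, "gaps") <- is.na(dF)
  class(out) <- c("profile1d", "data.frame")
  out
}
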