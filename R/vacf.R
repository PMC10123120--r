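#' Velocity autocorrelation function of an ensemble of trajectories
#'
#' Finite-difference velocities `u(t) = (r(t + delta) - r(t)) / delta` are
#' correlated at lag `tau`: `C(tau) = <u(t + tau) . u(t)>`, time-averaged
#' within each trajectory and then averaged across trajectories with equal
#' weight. The normalized curve `C(tau)/C(0)` of an antipersistent
#' (viscoelastic, FBM-like) process shows a negative peak at `tau = delta`,
#' whereas walks with uncorrelated steps (obstructed diffusion) stay at zero.
#'
#' @param trajs trajectory data.frame or list of them (regular frame grid).
#' @param delta velocity interval in frames (m >= 1; seconds are `m * dt`).
#' @param max_lag maximum correlation lag in frames; default `4 * delta`
#'   (enough to cover rescaled lags `xi = tau/delta` up to 4).
#' @param dt frame interval, s; inferred when absent.
#' @return object of class `vacf`: lag grid (`lags_s`), rescaled lags
#'   `xi = tau/delta`, raw `C` (nm^2/s^2), normalized `C_norm`, per-trajectory
#'   normalized values at `tau = delta` (`c_delta_traj`, for uncertainty
#'   estimates), `delta_s` and `n_traj`.
#' @seealso [fbm_vacf_theory()], [rescale_collapse()]
#' @export
vacf <- function(trajs, delta = 1L, max_lag = NULL, dt = NULL) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  delta <- as.integer(delta)
  stopifnot(delta >= 1L, length(trajs) >= 1L)
  if (is.null(dt)) dt <- .infer_dt(trajs[[1L]])
  if (is.null(max_lag)) max_lag <- 4L * delta
  grids <- lapply(trajs, .traj_grid)
  span <- min(vapply(grids, `[[`, 1L, "n"))
  if (delta > span / 4) {
    stop("delta exceeds a quarter of the shortest trajectory span")
  }
  lags <- 0:max_lag
  delta_s <- delta * dt
  per_traj <- vapply(grids, function(g) {
    n <- g$n
    iu <- seq_len(n - delta)
    ux <- (g$x[iu + delta] - g$x[iu]) / delta_s
    uy <- (g$y[iu + delta] - g$y[iu]) / delta_s
    nv <- length(ux)
    vapply(lags, function(j) {
      if (j >= nv) return(NA_real_)
      i <- seq_len(nv - j)
      v <- ux[i + j] * ux[i] + uy[i + j] * uy[i]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(lags)))
  per_traj <- matrix(per_traj, nrow = length(lags))
  n_ok <- rowSums(!is.na(per_traj))
  C <- rowMeans(per_traj, na.rm = TRUE)
  C[n_ok == 0L] <- NA_real_
  c0 <- per_traj[1L, ]
  c_delta_traj <- if (delta + 1L <= nrow(per_traj)) {
    per_traj[delta + 1L, ] / c0
  } else rep(NA_real_, ncol(per_traj))
  structure(
    list(delta_frames = delta, delta_s = delta_s, dt = dt,
         lags_s = lags * dt, xi = lags * dt / delta_s,
         C = C, C_norm = C / C[1L],
         c_delta_traj = c_delta_traj,
         n_traj = length(trajs)),
    class = "vacf"
  )
}

#' FBM velocity autocorrelation, closed form
#'
#' Normalized velocity autocorrelation predicted for fractional Brownian
#' motion as a function of the rescaled lag `xi = tau/delta`:
#' \deqn{C(\xi) = \{(\xi + 1)^{\alpha} + |\xi - 1|^{\alpha}
#'   - 2\xi^{\alpha}\}/2.}
#' All curves computed at different velocity intervals `delta` collapse onto
#' this single master curve when the process is self-similar; its minimum is
#' `(2^alpha - 2)/2` at `xi = 1`.
#'
#' @param xi rescaled lag(s), >= 0.
#' @param alpha scaling exponent in (0, 1].
#' @return normalized autocorrelation value(s).
#' @export
#' @examples
#' fbm_vacf_theory(1, 0.36) # about -0.358
fbm_vacf_theory <- function(xi, alpha) {
  stopifnot(all(xi >= 0), alpha > 0, alpha <= 1)
  ((xi + 1)^alpha + abs(xi - 1)^alpha - 2 * xi^alpha) / 2
}

#' Rescaling collapse of velocity autocorrelation curves
#'
#' Re-indexes normalized VACF curves measured at different velocity intervals
#' `delta` onto the common rescaled abscissa `xi = tau/delta` and quantifies
#' how well they collapse onto one master curve: the RMS spread across curves
#' at common `xi` values (linear interpolation), and optionally the RMS
#' deviation of the collapsed mean from the FBM closed form at a given
#' `alpha`.
#'
#' @param results list of >= 2 `vacf` objects with distinct `delta`.
#' @param alpha optional exponent at which to compare with
#'   [fbm_vacf_theory()].
#' @param xi_grid common rescaled-lag grid; defaults to 0..4 in steps of
#'   0.25, intersected with the overlap of the curves.
#' @return object of class `vacf_collapse`: the collapse table (`xi`, one
#'   column per `delta`, collapsed mean), `rms_spread`, and `rms_theory` when
#'   `alpha` is given.
#' @export
rescale_collapse <- function(results, alpha = NULL,
                             xi_grid = seq(0, 4, by = 0.25)) {
  stopifnot(is.list(results), length(results) >= 2L)
  if (!all(vapply(results, inherits, logical(1), "vacf"))) {
    stop("results must be a list of 'vacf' objects")
  }
  deltas <- vapply(results, `[[`, numeric(1), "delta_s")
  if (length(unique(deltas)) < 2L) stop("need >= 2 distinct delta values")
  lo <- max(vapply(results, function(r) min(r$xi), numeric(1)))
  hi <- min(vapply(results, function(r) max(r$xi), numeric(1)))
  if (hi <= lo) stop("vacf curves have non-overlapping xi ranges")
  grid <- xi_grid[xi_grid >= lo & xi_grid <= hi]
  if (length(grid) < 3L) stop("fewer than 3 common xi values after overlap")
  tab <- vapply(results, function(r) {
    ok <- is.finite(r$C_norm)
    stats::approx(r$xi[ok], r$C_norm[ok], xout = grid)$y
  }, numeric(length(grid)))
  tab <- matrix(tab, nrow = length(grid))
  colnames(tab) <- sprintf("delta_%gs", deltas)
  mean_curve <- rowMeans(tab)
  dev <- sweep(tab, 1L, mean_curve)
  rms_spread <- sqrt(mean(dev^2))
  rms_theory <- if (!is.null(alpha)) {
    sqrt(mean((mean_curve - fbm_vacf_theory(grid, alpha))^2))
  } else NA_real_
  structure(
    list(xi = grid, curves = tab, mean = mean_curve,
         rms_spread = rms_spread, rms_theory = rms_theory,
         alpha = alpha, deltas_s = deltas),
    class = "vacf_collapse"
  )
}

#' @export
print.vacf_collapse <- function(x, ...) {
  cat(sprintf("VACF rescaling collapse over delta = {%s} s\n",
              paste(signif(x$deltas_s, 4), collapse = ", ")))
  cat(sprintf("  RMS spread across curves: %.4f\n", x$rms_spread))
  if (!is.na(x$rms_theory)) {
    cat(sprintf("  RMS deviation from FBM form (alpha = %.3g): %.4f\n",
                x$alpha, x$rms_theory))
  }
  invisible(x)
}

#' Plot normalized VACF curves against the rescaled lag
#'
#' @param x a `vacf` object or (via [rescale_collapse()]) `vacf_collapse`.
#' @param alpha optional exponent for the FBM master-curve overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vacf <- function(x, alpha = NULL, ...) {
  graphics::plot(x$xi, x$C_norm, type = "b", pch = 16,
                 xlab = expression(xi == tau / delta),
                 ylab = expression(C[u]^delta * (tau) / C[u]^delta * (0)), ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(alpha)) {
    xx <- seq(min(x$xi), max(x$xi), length.out = 200)
    graphics::lines(xx, fbm_vacf_theory(xx, alpha), col = "red3")
  }
  invisible(x)
}

#' @export
plot.vacf_collapse <- function(x, ...) {
  graphics::plot(range(x$xi), range(x$curves, na.rm = TRUE), type = "n",
                 xlab = expression(xi == tau / delta),
                 ylab = "normalized VACF", ...)
  for (j in seq_len(ncol(x$curves))) {
    graphics::lines(x$xi, x$curves[, j], col = j + 1)
  }
  if (!is.null(x$alpha)) {
    graphics::lines(x$xi, fbm_vacf_theory(x$xi, x$alpha), lwd = 2)
  }
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
print.vacf <- function(x, ...) {
  cat(sprintf(
    "VACF: delta = %.3g s (%d frames), %d lags, %d trajectories\n",
    x$delta_s, x$delta_frames, length(x$lags_s), x$n_traj))
  i1 <- x$delta_frames + 1L
  if (i1 <= length(x$C_norm)) {
    cat(sprintf("  normalized C at tau = delta: %.3f\n", x$C_norm[i1]))
  }
  invisible(x)
}
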