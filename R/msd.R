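#' @keywords internal
# Expand a trajectory data.frame onto the full regular frame grid; gap frames
# become NA rows so lagged differences pair only co-observed frames.
.traj_grid <- function(traj) {
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(traj)))
  f <- as.integer(traj$frame)
  if (anyDuplicated(f)) stop("duplicated frames in trajectory")
  if (is.unsorted(f)) {
    o <- order(f)
    traj <- traj[o, ]
    f <- f[o]
  }
  full <- seq(f[1L], f[length(f)])
  x <- rep(NA_real_, length(full))
  y <- x
  idx <- f - f[1L] + 1L
  x[idx] <- traj$x_nm
  y[idx] <- traj$y_nm
  list(x = x, y = y, n = length(full))
}

.component_disp2 <- function(g, k, component) {
  n <- g$n
  i <- seq_len(n - k)
  dx <- g$x[i + k] - g$x[i]
  dy <- g$y[i + k] - g$y[i]
  switch(component,
    r2d = dx^2 + dy^2,
    x = dx^2,
    y = dy^2,
    stop("unknown component: ", component)
  )
}

.msd_obj <- function(component, lag_frames, dt, msd, n_pairs, mode,
                     curves = NULL) {
  structure(
    list(component = component, lag_frames = lag_frames,
         lags_s = lag_frames * dt, dt = dt, msd = msd, n_pairs = n_pairs,
         mode = mode, curves = curves),
    class = "msd"
  )
}

#' Time-averaged mean square displacement
#'
#' Computes the TA-MSD of one trajectory or of a list of trajectories with a
#' sliding (overlapping) time window: at lag `k*dt`, the average squared
#' displacement over all valid start times. Component `"r2d"` is the full 2D
#' displacement; `"x"` / `"y"` are the transversal / longitudinal axes. Frames
#' absent from the trajectory (linking gaps) are excluded pairwise. For a list
#' input, per-trajectory curves are kept and the ensemble mean is the
#' equal-weight average across trajectories at each lag.
#'
#' @param traj a trajectory data.frame (`frame`, `time_s`, `x_nm`, `y_nm`) or
#'   a list of them sharing one frame interval.
#' @param component `"r2d"`, `"x"` or `"y"`.
#' @param max_lag maximum lag in frames; defaults to a quarter of the
#'   trajectory length.
#' @param dt frame interval, s; inferred from `time_s` when absent.
#' @return an object of class `msd`; for list input, `$curves` holds the
#'   per-trajectory lag-by-trajectory matrix.
#' @seealso [ea_msd()], [fit_power_law()]
#' @export
ta_msd <- function(traj, component = c("r2d", "x", "y"), max_lag = NULL,
                   dt = NULL) {
  component <- match.arg(component)
  if (is.data.frame(traj)) traj <- list(traj)
  stopifnot(length(traj) >= 1L)
  if (is.null(dt)) dt <- .infer_dt(traj[[1L]])
  grids <- lapply(traj, .traj_grid)
  if (is.null(max_lag)) {
    max_lag <- max(1L, floor(max(vapply(grids, `[[`, 1L, "n")) / 4))
  }
  lags <- seq_len(max_lag)
  curves <- vapply(grids, function(g) {
    vapply(lags, function(k) {
      if (k >= g$n) return(NA_real_)
      d2 <- .component_disp2(g, k, component)
      if (all(is.na(d2))) NA_real_ else mean(d2, na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(lags)))
  curves <- matrix(curves, nrow = length(lags))
  n_pairs <- rowSums(!is.na(curves))
  m <- rowMeans(curves, na.rm = TRUE)
  m[n_pairs == 0L] <- NA_real_
  .msd_obj(component, lags, dt, m, n_pairs, "time",
           curves = if (ncol(curves) > 1L) curves else NULL)
}

#' Ensemble-averaged mean square displacement
#'
#' EA-MSD across trajectories: at lag `k*dt`, the mean over trajectories of
#' the squared displacement from each trajectory's first observed frame (no
#' time averaging). Comparing this with the time-averaged MSD of [ta_msd()]
#' is the ergodicity diagnostic that rules out ageing mechanisms such as
#' heavy-tailed CTRWs.
#'
#' @param trajs list of >= 10 trajectory data.frames with identical frame
#'   interval.
#' @inheritParams ta_msd
#' @return an object of class `msd` with `mode = "ensemble"`.
#' @export
ea_msd <- function(trajs, component = c("r2d", "x", "y"), max_lag = NULL,
                   dt = NULL) {
  component <- match.arg(component)
  stopifnot(is.list(trajs), length(trajs) >= 10L)
  dts <- vapply(trajs, .infer_dt, numeric(1))
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("trajectories have unequal frame intervals")
  }
  if (is.null(dt)) dt <- dts[1L]
  grids <- lapply(trajs, .traj_grid)
  if (is.null(max_lag)) {
    max_lag <- max(1L, floor(max(vapply(grids, `[[`, 1L, "n")) / 4))
  }
  lags <- seq_len(max_lag)
  d2 <- vapply(grids, function(g) {
    vapply(lags, function(k) {
      if (k >= g$n) return(NA_real_)
      dx <- g$x[1L + k] - g$x[1L]
      dy <- g$y[1L + k] - g$y[1L]
      switch(component, r2d = dx^2 + dy^2, x = dx^2, y = dy^2)
    }, numeric(1))
  }, numeric(length(lags)))
  d2 <- matrix(d2, nrow = length(lags))
  n_pairs <- rowSums(!is.na(d2))
  m <- rowMeans(d2, na.rm = TRUE)
  m[n_pairs == 0L] <- NA_real_
  .msd_obj(component, lags, dt, m, n_pairs, "ensemble")
}

.infer_dt <- function(traj) {
  if (!is.null(attr(traj, "dt"))) return(attr(traj, "dt"))
  if ("time_s" %in% names(traj) && nrow(traj) >= 2L) {
    d <- diff(traj$time_s) / diff(as.integer(traj$frame))
    return(stats::median(d))
  }
  stop("cannot infer frame interval; supply dt")
}

#' Fit a power law MSD = D * tau^alpha
#'
#' Ordinary least squares of `log(msd)` on `log(tau)` over a chosen lag
#' range; the slope estimates the scaling exponent `alpha` and the intercept
#' `log(D)`. The default range starts at lag 2 because on image-derived data
#' the localization-noise floor inflates lag 1; on noise-free simulated input
#' the fitted values are range-invariant.
#'
#' @param msd an `msd` object ([ta_msd()] / [ea_msd()]), or a data.frame with
#'   columns `lags_s` and `msd`.
#' @param lag_range integer lag indices (in frames) to fit, default `2:10`.
#' @return an object of class `powerlaw_fit` with components `D`, `alpha`,
#'   `se_alpha`, `se_logD`, the underlying `lm` fit, and the lag range;
#'   supports `print`, `coef`, `summary`, `predict` and `plot` (via
#'   [plot.msd()]).
#' @export
#' @examples
#' m <- ta_msd(simulate_trajectory(sim_config(n_frames = 200), seed = 1))
#' fit <- fit_power_law(m)
#' coef(fit)
fit_power_law <- function(msd, lag_range = 2:10) {
  if (is.data.frame(msd)) {
    tau <- msd$lags_s
    val <- msd$msd
    lag_frames <- seq_along(tau)
    component <- "r2d"
    dt <- if (length(tau) > 1) tau[2] - tau[1] else tau[1]
  } else {
    stopifnot(inherits(msd, "msd"))
    tau <- msd$lags_s
    val <- msd$msd
    lag_frames <- msd$lag_frames
    component <- msd$component
    dt <- msd$dt
  }
  keep <- lag_frames %in% lag_range & is.finite(val) & val > 0
  if (sum(keep) < sum(lag_frames %in% lag_range & is.finite(val))) {
    warning("non-positive MSD values dropped from fit range")
  }
  if (sum(keep) < 4L) stop("need >= 4 positive MSD values in lag range")
  fit <- stats::lm(log(val[keep]) ~ log(tau[keep]))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(D = unname(exp(cf[1L])), alpha = unname(cf[2L]),
         se_alpha = unname(se[2L]), se_logD = unname(se[1L]),
         lag_range = lag_range[lag_range %in% lag_frames[keep]],
         component = component, mode = if (is.data.frame(msd)) NA_character_ else msd$mode,
         lm = fit, tau = tau[keep], msd = val[keep], dt = dt),
    class = "powerlaw_fit"
  )
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(D = object$D, alpha = object$alpha)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law MSD fit: MSD = D * tau^alpha", "\n")
  cat(sprintf("  component: %s (%s-averaged), lags %d-%d\n",
              x$component, ifelse(identical(x$mode, "ensemble"), "ensemble",
                                  "time"),
              min(x$lag_range), max(x$lag_range)))
  cat(sprintf("  alpha = %.3f +/- %.3f\n", x$alpha, x$se_alpha))
  cat(sprintf("  D     = %.4g nm^2/s^alpha (log-scale SE %.3f)\n",
              x$D, x$se_logD))
  invisible(x)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  out <- list(
    coefficients = data.frame(
      estimate = c(object$D, object$alpha),
      se = c(object$D * object$se_logD, object$se_alpha),
      row.names = c("D", "alpha")
    ),
    walk_dimension = walk_fractal_dimension(object$alpha),
    lag_range = object$lag_range,
    r_squared = summary(object$lm)$r.squared
  )
  class(out) <- "summary.powerlaw_fit"
  out
}

#' @export
print.summary.powerlaw_fit <- function(x, ...) {
  cat("Power-law MSD fit summary\n")
  print(x$coefficients)
  cat(sprintf("walk dimension d_w = 2/alpha = %.2f (%s exploration)\n",
              x$walk_dimension$d_w,
              ifelse(x$walk_dimension$compact, "compact", "non-compact")))
  cat(sprintf("R^2 = %.4f on lags %d-%d\n", x$r_squared,
              min(x$lag_range), max(x$lag_range)))
  invisible(x)
}

#' @export
predict.powerlaw_fit <- function(object, tau = NULL, ...) {
  if (is.null(tau)) tau <- object$tau
  object$D * tau^object$alpha
}

#' Plot an MSD curve with an optional power-law fit
#'
#' Log-log plot of the (ensemble-mean) MSD against lag time; individual
#' trajectory curves, when present, are drawn in grey.
#'
#' @param x an `msd` object.
#' @param fit optional `powerlaw_fit` overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.msd <- function(x, fit = NULL, ...) {
  ok <- is.finite(x$msd) & x$msd > 0
  graphics::plot(x$lags_s[ok], x$msd[ok], log = "xy",
                 xlab = expression(tau ~ "(s)"),
                 ylab = expression(MSD ~ (nm^2)),
                 type = "n", ...)
  if (!is.null(x$curves)) {
    for (j in seq_len(ncol(x$curves))) {
      cv <- x$curves[, j]
      okj <- is.finite(cv) & cv > 0
      graphics::lines(x$lags_s[okj], cv[okj], col = "grey80")
    }
  }
  graphics::points(x$lags_s[ok], x$msd[ok], pch = 16)
  if (!is.null(fit)) {
    graphics::lines(x$lags_s[ok], predict(fit, x$lags_s[ok]), col = "red3",
                    lwd = 2)
  }
  invisible(x)
}

#' @export
print.msd <- function(x, ...) {
  cat(sprintf("MSD (%s-averaged, component %s): %d lags, dt = %.3g s\n",
              x$mode, x$component, length(x$lag_frames), x$dt))
  if (!is.null(x$curves)) {
    cat(sprintf("  %d trajectories\n", ncol(x$curves)))
  }
  invisible(x)
}
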