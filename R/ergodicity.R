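#' Ergodicity diagnostic: time- vs ensemble-averaged MSD
#'
#' Fits the power law `MSD = D * tau^alpha` to both the ensemble mean of the
#' time-averaged MSD and the ensemble-averaged MSD of the same trajectories,
#' and compares the exponents. Ergodic processes (Brownian motion, FBM) give
#' matching exponents; ageing processes such as heavy-tailed CTRWs give a
#' near-linear time-averaged MSD but a sublinear ensemble-averaged one, so a
#' large exponent gap rules the class in or out.
#'
#' The verdict is `"consistent"` when `|alpha_TA - alpha_EA|` is within
#' `max(3 * combined SE, 0.2)`; the 0.2 floor is the midpoint between the
#' zero gap expected for FBM and the gap `1 - beta = 0.5` expected for the
#' default CTRW alternative, and guards against the optimism of OLS standard
#' errors on correlated log-log points.
#'
#' @param trajs list of trajectories (>= 10).
#' @param component `"r2d"`, `"x"` or `"y"`.
#' @param fit_lags lag indices used for both fits.
#' @param gap_floor minimum exponent gap treated as evidence of
#'   non-ergodicity.
#' @return object of class `ergodicity_report`: both `powerlaw_fit`s, the
#'   exponent difference with propagated SE, and `verdict`.
#' @export
ergodicity_report <- function(trajs, component = c("r2d", "x", "y"),
                              fit_lags = 2:10, gap_floor = 0.2) {
  component <- match.arg(component)
  ta <- ta_msd(trajs, component = component)
  ea <- ea_msd(trajs, component = component)
  fit_ta <- fit_power_law(ta, lag_range = fit_lags)
  fit_ea <- fit_power_law(ea, lag_range = fit_lags)
  d_alpha <- fit_ta$alpha - fit_ea$alpha
  se <- sqrt(fit_ta$se_alpha^2 + fit_ea$se_alpha^2)
  consistent <- abs(d_alpha) <= max(3 * se, gap_floor)
  structure(
    list(component = component, ta_fit = fit_ta, ea_fit = fit_ea,
         delta_alpha = d_alpha, se_delta_alpha = se,
         delta_D = fit_ta$D - fit_ea$D,
         verdict = if (consistent) "consistent" else "inconsistent",
         gap_floor = gap_floor, fit_lags = fit_lags),
    class = "ergodicity_report"
  )
}

#' @export
print.ergodicity_report <- function(x, ...) {
  cat(sprintf("Ergodicity report (component %s, lags %d-%d)\n",
              x$component, min(x$fit_lags), max(x$fit_lags)))
  cat(sprintf("  TA fit: alpha = %.3f +/- %.3f, D = %.4g\n",
              x$ta_fit$alpha, x$ta_fit$se_alpha, x$ta_fit$D))
  cat(sprintf("  EA fit: alpha = %.3f +/- %.3f, D = %.4g\n",
              x$ea_fit$alpha, x$ea_fit$se_alpha, x$ea_fit$D))
  cat(sprintf("  delta alpha = %.3f +/- %.3f -> %s with ergodicity\n",
              x$delta_alpha, x$se_delta_alpha, x$verdict))
  invisible(x)
}

#' Walk (fractal) dimension of an anomalous random walk
#'
#' `d_w = 2/alpha`; a walk with `d_w` larger than the embedding dimension 2
#' explores space compactly (is space-filling), which makes the search for a
#' fixed target thorough rather than hit-or-miss.
#'
#' @param alpha scaling exponent, > 0.
#' @return list with `d_w` and logical `compact` (`d_w > 2`).
#' @export
#' @examples
#' walk_fractal_dimension(0.36) # d_w about 5.6, compact
walk_fractal_dimension <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0)) stop("alpha must be > 0")
  d_w <- 2 / alpha
  list(d_w = d_w, compact = d_w > 2)
}
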