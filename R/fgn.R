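#' Autocovariance of fractional Gaussian noise increments
#'
#' Autocovariance at integer lag `k` of the stationary increment series of
#' fractional Brownian motion sampled every `dt` seconds, parameterised so
#' that the ensemble MSD of the cumulative sum is exactly `D * (k*dt)^alpha`:
#' \deqn{\gamma(k) = \frac{D\,dt^{\alpha}}{2}\left(|k+1|^{\alpha}
#'   - 2|k|^{\alpha} + |k-1|^{\alpha}\right).}
#' `alpha = 2H` where `H` is the Hurst exponent; `alpha < 1` gives negatively
#' correlated (antipersistent) increments, `alpha = 1` ordinary Brownian
#' motion.
#'
#' @param k integer lag(s), >= 0.
#' @param alpha scaling exponent in (0, 1].
#' @param D apparent diffusion coefficient, nm^2 / s^alpha.
#' @param dt sampling interval, s.
#' @return numeric vector of autocovariances, nm^2.
#' @export
#' @examples
#' fgn_autocov(0:3, alpha = 0.5, D = 1, dt = 1)
fgn_autocov <- function(k, alpha, D = 1, dt = 1) {
  stopifnot(alpha > 0, alpha <= 1, D >= 0, dt > 0, all(k >= 0))
  (D * dt^alpha / 2) * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

# Davies-Harte / circulant-embedding sampler for a stationary Gaussian series
# with autocovariance g[1..n] = gamma(0..n-1). Returns NULL when the circulant
# eigenvalues are materially negative (caller falls back to Cholesky).
.fgn_circulant <- function(n, gamma_fun) {
  m <- 2 * n
  g <- gamma_fun(0:n)                    # gamma(0) .. gamma(n)
  row <- c(g, rev(g[2:n]))               # circulant first row, length 2n
  lam <- Re(stats::fft(row))
  if (min(lam) < -1e-8 * max(abs(lam))) {
    return(NULL)
  }
  lam[lam < 0] <- 0
  half <- n
  zr <- stats::rnorm(half + 1)
  zi <- stats::rnorm(half + 1)
  v <- complex(real = numeric(m), imaginary = numeric(m))
  v[1] <- sqrt(lam[1]) * zr[1]
  v[half + 1] <- sqrt(lam[half + 1]) * zr[half + 1]
  j <- seq(2, half)
  v[j] <- sqrt(lam[j] / 2) * complex(real = zr[j], imaginary = zi[j])
  v[m + 2 - j] <- Conj(v[j])
  x <- Re(stats::fft(v)) / sqrt(m)
  x[seq_len(n)]
}

# Exact Cholesky sampler; O(n^2) memory, used only as a fallback at small n.
.fgn_cholesky <- function(n, gamma_fun) {
  g <- gamma_fun(0:(n - 1))
  S <- stats::toeplitz(g)
  L <- tryCatch(chol(S), error = function(e) {
    stop("fGn covariance is not positive definite: ", conditionMessage(e))
  })
  as.numeric(crossprod(L, stats::rnorm(n)))
}

#' Simulate one axis of fractional Gaussian noise increments
#'
#' Draws an exact stationary Gaussian increment series with the fGn
#' autocovariance of [fgn_autocov()], by circulant embedding (O(n log n))
#' with a Cholesky fallback, so that the cumulative sum is a fractional
#' Brownian motion path with ensemble MSD `D * tau^alpha` at every lag.
#'
#' @inheritParams fgn_autocov
#' @param n_frames number of trajectory frames (>= 2); `n_frames - 1`
#'   increments are returned.
#' @param seed optional integer seed (identical seed, identical series).
#' @return numeric vector of `n_frames - 1` increments, nm.
#' @export
#' @examples
#' dx <- simulate_fgn_axis(alpha = 0.5, D = 1, dt = 1, n_frames = 100, seed = 1)
#' x <- c(0, cumsum(dx)) # an FBM path
simulate_fgn_axis <- function(alpha, D, dt, n_frames, seed = NULL) {
  stopifnot(alpha > 0, alpha <= 1, D >= 0, dt > 0, n_frames >= 2)
  n <- as.integer(n_frames) - 1L
  gfun <- function(k) fgn_autocov(k, alpha, D, dt)
  with_seed(seed, {
    if (n < 2L) {
      stats::rnorm(n, sd = sqrt(gfun(0)))
    } else {
      x <- .fgn_circulant(n, gfun)
      if (is.null(x)) x <- .fgn_cholesky(n, gfun)
      x
    }
  })
}
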