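#' Configuration for single-trajectory simulations
#'
#' Bundles the parameters of the stochastic motion models. Axes are
#' independent, each with its own scaling exponent and apparent diffusion
#' coefficient, emulating the anisotropy of locus motion along vs across a
#' rod-shaped cell.
#'
#' @param model one of `"fbm"` (fractional Brownian motion, exact fGn
#'   increments), `"ctrw"` (continuous-time random walk with Pareto waiting
#'   times, sampled on the regular frame grid) or `"od"` (nearest-neighbour
#'   lattice walk among fixed reflecting obstacles).
#' @param alpha_x,alpha_y scaling exponents in (0, 1] (transversal,
#'   longitudinal).
#' @param D_x,D_y apparent diffusion coefficients, nm^2/s^alpha.
#' @param dt frame interval, s.
#' @param n_frames frames per trajectory (>= 2).
#' @param n_traj number of trajectories.
#' @param seed integer master seed.
#' @param ctrw_beta waiting-time tail exponent in (0, 1); smaller = heavier
#'   tail = stronger ageing.
#' @param ctrw_t0 waiting-time scale (minimum wait), s; defaults to `dt/100`
#'   so the ageing regime is already developed at the first frame lag.
#' @param od_obstacle_density obstacle site fraction in `[0, 1)`.
#' @param od_lattice_nm lattice constant of the obstructed walk, nm.
#' @param od_steps_per_frame attempted lattice moves per frame.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(model = c("fbm", "ctrw", "od"),
                       alpha_x = 0.5, alpha_y = 0.5,
                       D_x = 2000, D_y = 2000,
                       dt = 4.23, n_frames = 90, n_traj = 1, seed = 1L,
                       ctrw_beta = 0.5, ctrw_t0 = NULL,
                       od_obstacle_density = 0.35,
                       od_lattice_nm = 20, od_steps_per_frame = 10L) {
  model <- match.arg(model)
  stopifnot(
    alpha_x > 0, alpha_x <= 1, alpha_y > 0, alpha_y <= 1,
    D_x >= 0, D_y >= 0, dt > 0, n_frames >= 2, n_traj >= 1,
    ctrw_beta > 0, ctrw_beta < 1, is.null(ctrw_t0) || ctrw_t0 > 0,
    od_obstacle_density >= 0, od_obstacle_density < 1
  )
  structure(
    list(
      model = model, alpha_x = alpha_x, alpha_y = alpha_y,
      D_x = D_x, D_y = D_y, dt = dt,
      n_frames = as.integer(n_frames), n_traj = as.integer(n_traj),
      seed = as.integer(seed), ctrw_beta = ctrw_beta,
      ctrw_t0 = if (is.null(ctrw_t0)) dt / 100 else ctrw_t0,
      od_obstacle_density = od_obstacle_density,
      od_lattice_nm = od_lattice_nm,
      od_steps_per_frame = as.integer(od_steps_per_frame)
    ),
    class = "sim_config"
  )
}

.traj_df <- function(frame, time_s, x, y) {
  data.frame(frame = frame, time_s = time_s, x_nm = x, y_nm = y)
}

.sim_fbm <- function(cfg) {
  n <- cfg$n_frames
  x <- c(0, cumsum(simulate_fgn_axis(cfg$alpha_x, cfg$D_x, cfg$dt, n)))
  y <- c(0, cumsum(simulate_fgn_axis(cfg$alpha_y, cfg$D_y, cfg$dt, n)))
  .traj_df(seq_len(n) - 1L, (seq_len(n) - 1L) * cfg$dt, x, y)
}

# Renewal CTRW: Pareto waiting times w = t0 * U^(-1/beta) (infinite mean for
# beta < 1), independent Gaussian jumps at each renewal, observed on the
# regular frame grid (position held between renewals). t0 << dt puts the
# frame lags deep in the ageing regime where EA-MSD ~ t^beta.
.sim_ctrw <- function(cfg) {
  n <- cfg$n_frames
  t_end <- (n - 1) * cfg$dt
  t0 <- cfg$ctrw_t0
  jump_sd_x <- sqrt(cfg$D_x * t0)
  jump_sd_y <- sqrt(cfg$D_y * t0)
  t_r <- 0
  renew_t <- numeric(0)
  repeat {
    w <- t0 * stats::runif(256)^(-1 / cfg$ctrw_beta)
    tt <- t_r + cumsum(w)
    renew_t <- c(renew_t, tt[tt <= t_end])
    t_r <- tt[length(tt)]
    if (t_r > t_end) break
  }
  k <- length(renew_t)
  jx <- c(0, cumsum(stats::rnorm(k, sd = jump_sd_x)))
  jy <- c(0, cumsum(stats::rnorm(k, sd = jump_sd_y)))
  grid <- (seq_len(n) - 1L) * cfg$dt
  idx <- findInterval(grid, renew_t) + 1L  # position after last renewal <= t
  .traj_df(seq_len(n) - 1L, grid, jx[idx], jy[idx])
}

# Obstructed diffusion: nearest-neighbour walk on a square lattice with a
# quenched fraction of blocked sites; blocked moves are rejected. Lattice
# indices wrap on a large torus so the walker never leaves the obstacle field.
.sim_od <- function(cfg) {
  n <- cfg$n_frames
  side <- 201L
  blocked <- matrix(stats::runif(side * side) < cfg$od_obstacle_density,
                    side, side)
  cx <- cy <- (side + 1L) %/% 2L
  blocked[cx, cy] <- FALSE
  pos <- matrix(0L, n, 2L)
  ix <- cx; iy <- cy
  moves <- matrix(c(1L, 0L, -1L, 0L, 0L, 1L, 0L, -1L), 4L, 2L, byrow = TRUE)
  nstep <- cfg$od_steps_per_frame
  pick <- sample.int(4L, (n - 1L) * nstep, replace = TRUE)
  s <- 0L
  offx <- 0L; offy <- 0L  # unwrapped offsets across torus wraps
  for (f in 2:n) {
    for (m in seq_len(nstep)) {
      s <- s + 1L
      nx <- ix + moves[pick[s], 1L]
      ny <- iy + moves[pick[s], 2L]
      wx <- 0L; wy <- 0L
      if (nx < 1L) { nx <- side; wx <- -side } else if (nx > side) { nx <- 1L; wx <- side }
      if (ny < 1L) { ny <- side; wy <- -side } else if (ny > side) { ny <- 1L; wy <- side }
      if (!blocked[nx, ny]) {
        ix <- nx; iy <- ny; offx <- offx + wx; offy <- offy + wy
      }
    }
    pos[f, ] <- c(ix - cx + offx, iy - cy + offy)
  }
  a <- cfg$od_lattice_nm
  .traj_df(seq_len(n) - 1L, (seq_len(n) - 1L) * cfg$dt,
           pos[, 1L] * a, pos[, 2L] * a)
}

#' Simulate a single 2D trajectory
#'
#' Generates one trajectory under the configured motion model, with
#' independent x (transversal) and y (longitudinal) axes.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return data.frame with columns `frame`, `time_s`, `x_nm`, `y_nm`.
#' @export
#' @examples
#' cfg <- sim_config("fbm", alpha_x = 0.36, alpha_y = 0.36, n_frames = 50)
#' tr <- simulate_trajectory(cfg, seed = 1)
simulate_trajectory <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  with_seed(seed, switch(cfg$model,
    fbm = .sim_fbm(cfg),
    ctrw = .sim_ctrw(cfg),
    od = .sim_od(cfg),
    stop("unknown model: ", cfg$model)
  ))
}

#' Simulate an ensemble of trajectories
#'
#' Runs [simulate_trajectory()] `cfg$n_traj` times with per-trajectory
#' sub-seeds derived from the master seed via [sub_seed()].
#'
#' @inheritParams simulate_trajectory
#' @return list of trajectory data.frames.
#' @export
simulate_trajectories <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  lapply(seq_len(cfg$n_traj), function(i) {
    simulate_trajectory(cfg, seed = sub_seed(seed, i))
  })
}
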