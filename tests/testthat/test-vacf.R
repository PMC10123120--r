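test_that("FBM theory curve evaluates the closed form", {
  expect_equal(fbm_vacf_theory(0, 0.7), 1)
  expect_equal(fbm_vacf_theory(1, 1), 0)
  expect_equal(fbm_vacf_theory(1, 0.36), (2^0.36 - 2) / 2)
  expect_equal(fbm_vacf_theory(1, 0.36), -0.3583, tolerance = 1e-4)
  # minimum of the curve sits at xi = 1 for alpha < 1
  xi <- seq(0, 4, by = 0.05)
  expect_equal(xi[which.min(fbm_vacf_theory(xi, 0.5))], 1)
  expect_error(fbm_vacf_theory(-1, 0.5))
})

test_that("measured VACF matches FBM theory at the antipersistence dip", {
  cfg <- sim_config("fbm", alpha_x = 0.36, alpha_y = 0.36, D_x = 2000,
                    D_y = 2000, dt = 4.23, n_frames = 150, n_traj = 200,
                    seed = 21)
  trajs <- simulate_trajectories(cfg)
  v <- vacf(trajs, delta = 1)
  expect_equal(v$C_norm[1], 1)
  # negative minimum exactly at tau = delta
  expect_lt(v$C_norm[2], 0)
  expect_equal(which.min(v$C_norm), 2L)
  se <- stats::sd(v$c_delta_traj) / sqrt(length(v$c_delta_traj))
  expect_lt(abs(v$C_norm[2] - fbm_vacf_theory(1, 0.36)), 3 * se)
})

test_that("rescaled curves at several deltas collapse onto the master curve", {
  cfg <- sim_config("fbm", alpha_x = 0.36, alpha_y = 0.36, D_x = 2000,
                    D_y = 2000, dt = 4.23, n_frames = 200, n_traj = 200,
                    seed = 22)
  trajs <- simulate_trajectories(cfg)
  vl <- lapply(c(1, 2, 4, 8), function(m) vacf(trajs, delta = m))
  col <- rescale_collapse(vl, alpha = 0.36)
  expect_lt(col$rms_spread, 0.05)
  expect_lt(col$rms_theory, 0.05)
  expect_error(rescale_collapse(vl[1]), "2")
  expect_error(rescale_collapse(list(vl[[1]], vl[[1]])), "distinct")
})

test_that("CTRW velocities contradict the FBM form at its own subdiffusive exponent", {
  # an ageing CTRW is subdiffusive in the ensemble sense yet its steps are
  # uncorrelated, so its rescaled VACF sits on the uncorrelated (Brownian)
  # curve, far from the FBM prediction at the measured exponent; FBM
  # matches its own prediction
  n <- 150
  cfgc <- sim_config("ctrw", D_x = 2000, D_y = 2000, ctrw_beta = 0.5,
                     n_frames = n, n_traj = n, seed = 23)
  trc <- simulate_trajectories(cfgc)
  alpha_c <- fit_power_law(ea_msd(trc), lag_range = 2:10)$alpha
  expect_lt(alpha_c, 0.7) # strongly subdiffusive by EA-MSD
  vlc <- lapply(c(1, 2, 4), function(m) vacf(trc, delta = m))
  mis_c <- rescale_collapse(vlc, alpha = alpha_c)$rms_theory
  cfgf <- sim_config("fbm", alpha_x = 0.36, alpha_y = 0.36, D_x = 2000,
                     D_y = 2000, n_frames = n, n_traj = n, seed = 23)
  trf <- simulate_trajectories(cfgf)
  vlf <- lapply(c(1, 2, 4), function(m) vacf(trf, delta = m))
  mis_f <- rescale_collapse(vlf, alpha = 0.36)$rms_theory
  expect_gt(mis_c, 2 * mis_f)
  expect_lt(mis_f, 0.05)
})

test_that("delta exceeding a quarter of the span is rejected", {
  cfg <- sim_config("fbm", n_frames = 40, seed = 1)
  expect_error(vacf(simulate_trajectory(cfg), delta = 11), "quarter")
})
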