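test_that("TA-MSD of deterministic motion matches closed forms", {
  # ballistic along x: msd_x(k) = (k*s)^2
  s <- 3
  tr <- make_traj(x = s * (0:29), y = rep(0, 30))
  m <- ta_msd(tr, component = "x", max_lag = 7)
  expect_equal(m$msd, (s * (1:7))^2)
  # stationary trajectory
  m0 <- ta_msd(make_traj(x = rep(2, 25), y = rep(-1, 25)), max_lag = 6)
  expect_equal(m0$msd, rep(0, 6))
  # 2D msd is the sum of the axis msds (identical windows)
  tr2 <- make_traj(x = cumsum(rnorm(40)), y = cumsum(rnorm(40)))
  mr <- ta_msd(tr2, max_lag = 10)
  mx <- ta_msd(tr2, component = "x", max_lag = 10)
  my <- ta_msd(tr2, component = "y", max_lag = 10)
  expect_equal(mr$msd, mx$msd + my$msd)
})

test_that("TA-MSD equals the O(n^2) brute-force oracle exactly", {
  set.seed(71)
  fixtures <- list(
    make_traj(x = as.numeric(sample(-5:5, 30, TRUE)),
              y = as.numeric(sample(-5:5, 30, TRUE))),   # integer grid
    make_traj(x = cumsum(rnorm(50)), y = cumsum(rnorm(50))), # float
    { # trajectory with linking gaps
      tr <- make_traj(x = cumsum(rnorm(40)), y = cumsum(rnorm(40)))
      tr[-c(5, 6, 17, 30), ]
    }
  )
  for (tr in fixtures) {
    for (comp in c("r2d", "x", "y")) {
      expect_equal(ta_msd(tr, component = comp, max_lag = 9)$msd,
                   brute_ta_msd(tr, comp, 9))
    }
  }
})

test_that("EA-MSD of identical deterministic trajectories is the displacement curve", {
  tr <- make_traj(x = (0:20)^1.5, y = rep(0, 21))
  trajs <- replicate(12, tr, simplify = FALSE)
  m <- ea_msd(trajs, component = "x", max_lag = 5)
  expect_equal(m$msd, (tr$x_nm[2:6] - tr$x_nm[1])^2)
  expect_error(ea_msd(trajs[1:5]), "10")
})

test_that("EA and TA agree for FBM within sampling error", {
  cfg <- sim_config("fbm", alpha_x = 0.5, alpha_y = 0.5, D_x = 1000,
                    D_y = 1000, dt = 1, n_frames = 100, n_traj = 500,
                    seed = 12)
  trajs <- simulate_trajectories(cfg)
  ta <- ta_msd(trajs, max_lag = 10)
  ea <- ea_msd(trajs, max_lag = 10)
  # SE of the EA mean at each lag from the spread across trajectories
  for (k in 1:10) {
    d2 <- sapply(trajs, function(tr) {
      (tr$x_nm[1 + k] - tr$x_nm[1])^2 + (tr$y_nm[1 + k] - tr$y_nm[1])^2
    })
    se <- stats::sd(d2) / sqrt(length(d2))
    expect_lt(abs(ta$msd[k] - ea$msd[k]), 3 * se)
  }
})

test_that("power-law fit is exact on noiseless input and range-invariant", {
  lags <- 1:20
  fake <- structure(
    list(component = "r2d", lag_frames = lags, lags_s = lags * 1,
         dt = 1, msd = 4 * lags^0.5, n_pairs = rep(100, 20), mode = "time",
         curves = NULL),
    class = "msd")
  f1 <- suppressWarnings(fit_power_law(fake, lag_range = 2:10))
  expect_equal(coef(f1), c(D = 4, alpha = 0.5))
  f2 <- suppressWarnings(fit_power_law(fake, lag_range = 1:5))
  expect_equal(coef(f2), coef(f1))
  expect_equal(predict(f1, 4), 4 * 2)
  expect_error(fit_power_law(fake, lag_range = 1:3), ">= 4")
})

test_that("fitted exponent recovers the generating exponent across a sweep", {
  for (alpha in c(0.25, 0.5, 0.75, 1.0)) {
    cfg <- sim_config("fbm", alpha_x = alpha, alpha_y = alpha,
                      D_x = 2000, D_y = 2000, dt = 4.23, n_frames = 100,
                      n_traj = 100, seed = round(1000 * alpha))
    fit <- fit_power_law(ta_msd(simulate_trajectories(cfg)),
                         lag_range = 2:10)
    expect_lt(abs(fit$alpha - alpha), 3 * max(fit$se_alpha, 0.015))
  }
})

test_that("msd and fit objects print and plot without error", {
  cfg <- sim_config("fbm", n_frames = 60, n_traj = 5, seed = 2)
  m <- ta_msd(simulate_trajectories(cfg))
  f <- fit_power_law(m)
  expect_output(print(m), "MSD")
  expect_output(print(f), "alpha")
  expect_output(print(summary(f)), "walk dimension")
  tmp <- tempfile(fileext = ".svg")
  grDevices::svg(tmp)
  expect_silent(plot(m, fit = f))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})
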