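test_that("the decision cascade assigns each constructed archetype", {
  L <- 3000
  n <- 60
  f <- 0:(n - 1)
  still <- rep(0, n)
  # integrated: sits 200 nm from attB throughout
  ice_int <- make_traj(x = rep(200, n), y = still, frame = f)
  attb <- make_traj(x = still, y = still, frame = f)
  d <- nearest_attb_distance(ice_int, list(attb))
  expect_identical(classify_ice(ice_int, d, L)$label, "integrated")
  # mobile_fast: large jumps and > 40% longitudinal span
  y_fast <- rep(c(-1300, 1300), n / 2)
  ice_fast <- make_traj(x = still, y = y_fast, frame = f)
  d_fast <- nearest_attb_distance(ice_fast, list(attb))
  cl_fast <- classify_ice(ice_fast, d_fast, L)
  expect_identical(cl_fast$label, "mobile_fast")
  expect_gt(cl_fast$evidence$span_frac, 0.4)
  # mobile_local: a 250 nm step among small ones, narrow span
  y_loc <- c(rep(0, 30), rep(250, 30))
  ice_loc <- make_traj(x = still, y = y_loc + 600, frame = f)
  d_loc <- nearest_attb_distance(ice_loc, list(attb))
  expect_identical(classify_ice(ice_loc, d_loc, L)$label, "mobile_local")
  # trapped: tiny motion far from attB
  ice_tr <- make_traj(x = rep(100, n), y = rep(900, n), frame = f)
  d_tr <- nearest_attb_distance(ice_tr, list(attb))
  cl_tr <- classify_ice(ice_tr, d_tr, L)
  expect_identical(cl_tr$label, "trapped")
  expect_lt(cl_tr$evidence$rg_nm, 150)
  # missing distance series restricts to mobility classes and flags
  cl_nf <- classify_ice(ice_int, NULL, L)
  expect_identical(cl_nf$label, "trapped")
  expect_match(cl_nf$flag, "not assessable")
})

test_that("classification is deterministic and order-independent", {
  cfg <- population_config(n_cells = 60, seed = 15)
  pop <- simulate_population(cfg)
  cl1 <- classify_population(pop$tracks, pop$cells)
  perm <- sample(nrow(pop$tracks))
  cl2 <- classify_population(pop$tracks[perm, ], pop$cells)
  expect_equal(cl1$fractions, cl2$fractions)
})

test_that("generated class fractions are recovered within binomial CIs", {
  cfg <- population_config(
    n_cells = 500,
    class_fractions = c(integrated = 0.40, mobile_fast = 0.20,
                        mobile_local = 0.25, trapped = 0.15),
    seed = 16)
  pop <- simulate_population(cfg)
  fr <- classify_population(pop$tracks, pop$cells)$fractions
  for (lab in names(cfg$class_fractions)) {
    p <- cfg$class_fractions[[lab]]
    ci <- 1.96 * sqrt(p * (1 - p) / 500)
    expect_lt(abs(fr$fraction[fr$label == lab] - p), ci + 1e-9,
              label = sprintf("fraction of %s", lab))
  }
})

test_that("mobility filter matches the exhaustive step oracle", {
  set.seed(44)
  trajs <- lapply(1:40, function(i) {
    n <- sample(10:60, 1)
    make_traj(x = cumsum(rnorm(n, sd = sample(c(20, 120), 1))),
              y = cumsum(rnorm(n, sd = sample(c(20, 120), 1))),
              frame = cumsum(sample(1:2, n, TRUE)))
  })
  kept <- mobility_filter(trajs, step_nm = 200)
  oracle <- Filter(function(tr) brute_has_big_step(tr, 200), trajs)
  expect_identical(kept, oracle)
  # trivial cases
  expect_length(mobility_filter(list(make_traj(x = rep(0, 30),
                                               y = rep(0, 30)))), 0)
  one_step <- make_traj(x = c(rep(0, 10), rep(250, 10)), y = rep(0, 20))
  expect_length(mobility_filter(list(one_step)), 1)
})

test_that("position distributions normalize, fold and find peaks", {
  lengths <- data.frame(cell_id = 1, length_nm = 2000)
  # all positions at the COM: a delta at 0.5
  tr <- make_traj(x = rep(0, 200), y = rep(0, 200))
  tr$cell_id <- 1
  pd <- position_distribution(list(tr), lengths, nbins = 21)
  expect_equal(pd$peaks[1], 0.5, tolerance = 0.03)
  expect_equal(sum(pd$counts), 200)
  # an asymmetric distribution folds symmetric
  tr2 <- make_traj(x = rep(0, 300), y = rep(-500, 300)) # fraction 0.25
  tr2$cell_id <- 1
  pdf_ <- position_distribution(list(tr2), lengths, nbins = 20, fold = TRUE)
  expect_equal(pdf_$counts, rev(pdf_$counts))
  # out-of-cell positions are dropped and counted
  tr3 <- make_traj(x = rep(0, 3), y = c(0, 1500, -1500))
  tr3$cell_id <- 1
  pd3 <- position_distribution(list(tr3), lengths)
  expect_equal(pd3$n_dropped, 2)
})

test_that("mobile ICE positions from the generator peak at mid-cell", {
  cfg <- population_config(n_cells = 80, n_frames = 40,
                           class_fractions = c(mobile_local = 0.6,
                                               mobile_fast = 0.4),
                           seed = 17)
  pop <- simulate_population(cfg)
  ice <- pop$tracks[pop$tracks$channel == "green", ]
  kept <- mobility_filter(split(ice, ice$cell_id), step_nm = 200)
  pd <- position_distribution(kept, pop$cells, nbins = 20)
  expect_lt(abs(pd$peaks[1] - 0.5), 0.05)
})
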