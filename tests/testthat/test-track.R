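make_det <- function(..., channel = "green", cell_id = 1L) {
  d <- data.frame(...)
  d$cell_id <- cell_id
  d$channel <- channel
  d$time_s <- d$frame * 4.23
  d
}

test_that("stationary spots link into full-length trajectories", {
  det <- make_det(
    frame = rep(0:49, each = 2),
    x_nm = rep(c(0, 50), 50),
    y_nm = rep(c(0, 1200), 50))
  tr <- link_trajectories(det, min_len = 20)
  expect_equal(length(unique(tr$locus_id)), 2)
  expect_equal(as.vector(table(tr$locus_id)), c(50, 50))
  # each track stays on its spot
  sp <- split(tr, tr$locus_id)
  expect_true(all(vapply(sp, function(d) diff(range(d$y_nm)) == 0,
                         logical(1))))
})

test_that("gap closing bridges short disappearances", {
  det <- make_det(frame = setdiff(0:39, 17), x_nm = 0, y_nm = 0)
  tr <- link_trajectories(det, max_gap = 2, min_len = 20)
  expect_equal(length(unique(tr$locus_id)), 1)
  expect_equal(nrow(tr), 39)
  # gap longer than max_gap splits the track; both halves kept if long enough
  det2 <- make_det(frame = setdiff(0:59, 25:29), x_nm = 0, y_nm = 0)
  tr2 <- link_trajectories(det2, max_gap = 2, min_len = 20)
  expect_equal(length(unique(tr2$locus_id)), 2)
})

test_that("displacements above max_disp are never linked", {
  det <- make_det(frame = 0:39, x_nm = 0,
                  y_nm = c(rep(0, 20), rep(3000, 20)))
  tr <- link_trajectories(det, max_disp = 800, min_len = 10)
  expect_equal(length(unique(tr$locus_id)), 2)
})

test_that("linking is invariant to detection row order", {
  set.seed(41)
  cfg <- sim_config("fbm", alpha_x = 0.5, alpha_y = 0.5, D_x = 500,
                    D_y = 500, n_frames = 40, seed = 3)
  t1 <- simulate_trajectory(cfg, seed = 10)
  t2 <- simulate_trajectory(cfg, seed = 11)
  t2$y_nm <- t2$y_nm + 1500
  det <- make_det(frame = c(t1$frame, t2$frame),
                  x_nm = c(t1$x_nm, t2$x_nm),
                  y_nm = c(t1$y_nm, t2$y_nm))
  perm <- sample(nrow(det))
  tr_a <- link_trajectories(det, min_len = 20)
  tr_b <- link_trajectories(det[perm, ], min_len = 20)
  key <- function(d) d[order(d$locus_id, d$frame),
                       c("frame", "x_nm", "y_nm")]
  expect_equal(key(tr_a), key(tr_b), ignore_attr = TRUE)
  # greedy and exhaustive-optimal agree on this two-spot stream
  tr_c <- link_trajectories(det, min_len = 20, method = "optimal")
  expect_equal(key(tr_c), key(tr_a), ignore_attr = TRUE)
})

test_that("links agree with ground-truth identities on rendered data", {
  cfg <- population_config(n_cells = 2, n_frames = 25,
                           class_fractions = c(integrated = 1), seed = 13)
  pop <- simulate_population(cfg, add_noise = FALSE)
  st <- render_stack(pop, frame_px = 230)
  det <- localize_stack(st, dt = cfg$dt)
  tr <- link_trajectories(det, min_len = 15)
  # per cell: two red tracks + one green track expected
  counts <- table(tr$cell_id, tr$channel) / 25
  expect_true(all(counts[, "red"] == 2))
  expect_true(all(counts[, "green"] == 1))
  # every red track stays near one truth attB locus (identity preserved)
  agree <- 0; total <- 0
  for (cid in unique(tr$cell_id)) {
    for (lid in unique(tr$locus_id[tr$cell_id == cid &
                                     tr$channel == "red"])) {
      d <- tr[tr$cell_id == cid & tr$channel == "red" &
                tr$locus_id == lid, ]
      truth <- pop$tracks[pop$tracks$cell_id == cid &
                            pop$tracks$channel == "red", ]
      # nearest truth locus per frame
      near <- sapply(seq_len(nrow(d)), function(i) {
        cand <- truth[truth$frame == d$frame[i], ]
        cand$locus_id[which.min((cand$x_nm - d$x_nm[i])^2 +
                                  (cand$y_nm - d$y_nm[i])^2)]
      })
      agree <- agree + max(table(near))
      total <- total + length(near)
    }
  }
  expect_gte(agree / total, 0.99)
})

test_that("nearest-attB distance follows the minimum rule", {
  ice <- make_traj(x = c(0, 0, 0), y = c(0, 0, 0))
  a1 <- make_traj(x = c(0, 0, 0), y = c(500, 500, 500))
  a2 <- make_traj(x = c(0, 0, 0), y = c(-300, -300, -300))
  d <- nearest_attb_distance(ice, list(a1, a2))
  expect_equal(d$d_nm, rep(300, 3))
  # identical trajectories give zero distance
  expect_equal(nearest_attb_distance(ice, list(ice))$d_nm, rep(0, 3))
  # no common frames is an error
  late <- make_traj(x = 0, y = 0, frame = 10L)
  expect_error(nearest_attb_distance(ice, list(late)), "common frames")
})

test_that("tethered pairs with localization noise read out near 200 nm", {
  cfg <- population_config(n_cells = 40, n_frames = 60,
                           class_fractions = c(integrated = 1), seed = 14)
  pop <- simulate_population(cfg, add_noise = TRUE) # 20 nm/axis noise
  mean_d <- sapply(split(pop$tracks, pop$tracks$cell_id), function(ct) {
    ice <- ct[ct$channel == "green", ]
    ab <- split(ct[ct$channel == "red", ], ct$locus_id[ct$channel == "red"])
    mean(nearest_attb_distance(ice, ab)$d_nm)
  })
  expect_equal(mean(mean_d), 200, tolerance = 0.15)
})
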