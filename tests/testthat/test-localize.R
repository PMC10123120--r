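# Rendered fixtures: a few separated cells in one frame.
multi_cell_frame <- function(n_cells = 3, noise = TRUE, seed = 9) {
  cfg <- population_config(n_cells = n_cells, n_frames = 2,
                           class_fractions = c(integrated = 1), seed = seed)
  pop <- simulate_population(cfg, add_noise = FALSE)
  st <- render_stack(pop, frame_px = 230, noise = noise)
  list(pop = pop, stack = st)
}

test_that("segmentation recovers cell count and geometry", {
  fx <- multi_cell_frame(3)
  geoms <- segment_cells(fx$stack$phase[, , 1])
  expect_length(geoms, 3)
  # lengths within 2 px of truth, width below length
  truth_L <- sort(fx$pop$cells$length_nm)
  est_L <- sort(vapply(geoms, `[[`, numeric(1), "length_nm"))
  expect_true(all(abs(est_L - truth_L) < 2 * 109.76))
  for (g in geoms) expect_gt(g$length_nm, g$width_nm)
})

test_that("blank frames and border cells are handled", {
  blank <- matrix(0.8, 64, 64)
  expect_warning(g <- segment_cells(blank + rnorm(64^2, sd = 0.01)),
                 "no cells")
  expect_length(g, 0)
  # a cell bisected by the frame edge is excluded
  fx <- multi_cell_frame(1)
  img <- fx$stack$phase[, , 1]
  geoms <- segment_cells(img)
  expect_length(geoms, 1)
  com <- geoms[[1]]$com_px
  cropped <- img[seq_len(round(com[2])), ] # cut through the cell
  expect_warning(gg <- segment_cells(cropped), "no cells")
  expect_length(gg, 0)
})

test_that("spot detection finds rendered spots and nothing in background", {
  fx <- multi_cell_frame(1)
  g <- segment_cells(fx$stack$phase[, , 1])[[1]]
  det_g <- detect_spots(fx$stack$green[, , 1], g)
  expect_equal(nrow(det_g), 1) # one ICE
  det_r <- detect_spots(fx$stack$red[, , 1], g)
  expect_equal(nrow(det_r), 2) # two attB
  # pure background: false positives < 0.01/cell over 100 noise draws
  set.seed(1)
  fp <- 0
  for (i in 1:100) {
    bg <- matrix(rpois(230^2, 100) + rnorm(230^2, sd = 2), 230, 230)
    fp <- fp + nrow(detect_spots(bg, g))
  }
  expect_lt(fp / 100, 0.01)
})

test_that("two spots ten pixels apart give two clusters", {
  img <- matrix(100, 64, 64)
  img <- locusdyn:::.add_spot(img, 20, 32, 1.2, 2000)
  img <- locusdyn:::.add_spot(img, 30, 32, 1.2, 2000)
  mask <- matrix(FALSE, 64, 64); mask[20:45, 10:40] <- TRUE
  g <- locusdyn:::.geom_from_mask(mask, 109.76)
  det <- detect_spots(img, g, threshold_k = 5)
  expect_equal(nrow(det), 2)
})

test_that("Gaussian fit is sub-pixel accurate and estimates the offset", {
  img <- matrix(50, 48, 48) # constant offset B = 50
  img <- locusdyn:::.add_spot(img, 20.30, 30.70, 1.2, 5000)
  ft <- fit_spot_gaussian(img, c(20, 31))
  expect_lt(abs(ft$x0 - 20.30), 0.05)
  expect_lt(abs(ft$y0 - 30.70), 0.05)
  expect_equal(ft$offset, 50, tolerance = 0.05)
  # spot at an exact pixel center
  img2 <- matrix(10, 32, 32)
  img2 <- locusdyn:::.add_spot(img2, 16, 16, 1.2, 3000)
  ft2 <- fit_spot_gaussian(img2, c(16, 16))
  expect_equal(c(ft2$x0, ft2$y0), c(16, 16), tolerance = 1e-3)
  # a flat window cannot be fit
  expect_null(fit_spot_gaussian(matrix(5, 32, 32), c(16, 16)))
})

test_that("localization precision at default noise is below 0.25 px", {
  set.seed(33)
  err <- replicate(150, {
    x0 <- 20 + runif(1); y0 <- 20 + runif(1)
    img <- matrix(100, 41, 41)
    img <- locusdyn:::.add_spot(img, x0, y0, 130 / 109.76, 2000)
    img <- matrix(rpois(41^2, img), 41, 41) + rnorm(41^2, sd = 2)
    ft <- fit_spot_gaussian(img, c(round(x0), round(y0)))
    c(ft$x0 - x0, ft$y0 - y0)
  })
  expect_lt(sd(err[1, ]), 0.25)
  expect_lt(sd(err[2, ]), 0.25)
})

test_that("cell-frame transform follows the stated geometry", {
  g <- straight_geom(cx = 20, cy = 10, half_len = 12)
  px <- 109.76
  # on the centerline at the COM
  cf <- to_cell_frame(c(20, 10), g)
  expect_equal(c(cf$x_nm, cf$y_nm), c(0, 0), tolerance = 1e-9)
  # 2 px above the centerline (image y down = left of +x direction is -y up;
  # sign is fixed by the frozen pole convention), 10 px right of the COM
  cf2 <- to_cell_frame(c(30, 12), g)
  expect_equal(abs(cf2$x_nm), 2 * px, tolerance = 1e-9)
  expect_equal(cf2$y_nm, 10 * px, tolerance = 1e-9)
  expect_false(cf2$clamped)
  # beyond the pole: clamped flag
  cf3 <- to_cell_frame(c(40, 10), g)
  expect_true(cf3$clamped)
})

test_that("cell-frame coordinates are invariant to rigid motions", {
  g <- straight_geom()
  pts <- list(c(25, 11.4), c(14.2, 9.1), c(20.5, 10))
  for (theta in c(0.3, 1.1, 2.5)) {
    gr <- rotate_geom(g, theta, shift = c(7, -3))
    for (p in pts) {
      a <- to_cell_frame(p, g)
      b <- to_cell_frame(rotate_pt(p, theta, shift = c(7, -3)), gr)
      expect_equal(b$x_nm, a$x_nm, tolerance = 0.05 * 109.76)
      expect_equal(b$y_nm, a$y_nm, tolerance = 0.05 * 109.76)
    }
  }
})

test_that("transform approximates COM distance for a gently curved cell", {
  # circular-arc centerline, small curvature
  R <- 200; px <- 109.76
  th <- seq(-0.1, 0.1, length.out = 41)
  cl <- cbind(x = R * sin(th), y = R * (1 - cos(th)))
  arc <- c(0, cumsum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)))
  g <- structure(
    list(id = 1L, com_px = c(0, 0), centerline_px = cl, arc_px = arc,
         com_arc_px = arc[21], length_nm = max(arc) * px,
         width_nm = 8 * px, pole_u = c(1, 0), pixel_size = px),
    class = "cell_geometry")
  p <- c(R * sin(0.07), R * (1 - cos(0.07)) + 1.5)
  cf <- to_cell_frame(p, g)
  eucl <- sqrt(sum(p^2)) * px
  expect_equal(sqrt(cf$x_nm^2 + cf$y_nm^2), eucl, tolerance = 0.05 * eucl)
})

test_that("end-to-end localization on a rendered stack is accurate", {
  cfg <- population_config(n_cells = 1, n_frames = 15,
                           class_fractions = c(integrated = 1), seed = 11)
  pop <- simulate_population(cfg, add_noise = FALSE)
  # noiseless: bias below 5 nm
  st0 <- render_stack(pop, frame_px = 96, noise = FALSE)
  det0 <- localize_stack(st0, dt = cfg$dt)
  err0 <- localization_errors(det0, pop)
  expect_lt(abs(mean(err0$dx)), 5)
  expect_lt(abs(mean(err0$dy)), 5)
  # default noise: per-axis RMSE below 25 nm
  st1 <- render_stack(pop, frame_px = 96, noise = TRUE)
  det1 <- localize_stack(st1, dt = cfg$dt)
  err1 <- localization_errors(det1, pop)
  expect_lt(sqrt(mean(err1$dx^2)), 25)
  expect_lt(sqrt(mean(err1$dy^2)), 25)
})
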