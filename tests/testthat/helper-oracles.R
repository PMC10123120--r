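# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately share no code with the package internals.

# O(n^2) TA-MSD: loop over every ordered pair (t, t + tau).
brute_ta_msd <- function(traj, component = "r2d", max_lag) {
  f <- traj$frame
  full <- seq(min(f), max(f))
  x <- rep(NA_real_, length(full)); y <- x
  x[f - min(f) + 1] <- traj$x_nm
  y[f - min(f) + 1] <- traj$y_nm
  n <- length(full)
  sapply(seq_len(max_lag), function(k) {
    acc <- c()
    for (t in seq_len(n - k)) {
      dx <- x[t + k] - x[t]; dy <- y[t + k] - y[t]
      if (!is.na(dx) && !is.na(dy)) {
        acc <- c(acc, switch(component, r2d = dx^2 + dy^2, x = dx^2,
                             y = dy^2))
      }
    }
    if (length(acc)) mean(acc) else NA_real_
  })
}

# Exhaustive per-step mobility check.
brute_has_big_step <- function(traj, step_nm = 200) {
  traj <- traj[order(traj$frame), ]
  for (i in seq_len(nrow(traj) - 1)) {
    if (traj$frame[i + 1] - traj$frame[i] == 1) {
      s <- sqrt((traj$x_nm[i + 1] - traj$x_nm[i])^2 +
                  (traj$y_nm[i + 1] - traj$y_nm[i])^2)
      if (s > step_nm) return(TRUE)
    }
  }
  FALSE
}

make_traj <- function(x, y, frame = seq_along(x) - 1L, dt = 1) {
  data.frame(frame = frame, time_s = frame * dt, x_nm = x, y_nm = y)
}

# Straight horizontal synthetic cell geometry (no imaging), for coordinate
# transform tests: centerline along +x through (cx, cy).
straight_geom <- function(cx = 20, cy = 10, half_len = 12, pixel_size = 109.76) {
  xs <- seq(cx - half_len, cx + half_len, by = 1)
  cl <- cbind(x = xs, y = rep(cy, length(xs)))
  arc <- c(0, cumsum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)))
  structure(
    list(id = 1L, mask = NULL, area_px = NA, com_px = c(cx, cy),
         centerline_px = cl, arc_px = arc, com_arc_px = half_len,
         length_nm = 2 * half_len * pixel_size,
         width_nm = 8 * pixel_size / 2, boundary_px = NULL,
         pole_u = c(1, 0), pixel_size = pixel_size),
    class = "cell_geometry")
}

# Rotate a cell_geometry and a set of points rigidly about the origin.
rotate_geom <- function(geom, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  tr <- function(p) sweep(p %*% t(R), 2, -shift)
  g <- geom
  g$centerline_px <- tr(geom$centerline_px)
  colnames(g$centerline_px) <- c("x", "y")
  g$com_px <- as.numeric(tr(matrix(geom$com_px, 1)))
  g$pole_u <- as.numeric(R %*% geom$pole_u)
  g
}

# Render a tethered two-channel pair and measure the fitted separation per
# frame (lab-frame distance between the green and red sub-pixel centers).
measured_pair_distance <- function(n_frames = 60, separation = 200,
                                   seed = 1) {
  truth <- simulate_tethered_pair(n_frames = n_frames,
                                  separation = separation, seed = seed)
  st <- render_stack(truth, frame_px = 96, seed = seed + 1)
  det <- localize_stack(st, dt = truth$config$dt)
  px <- truth$config$pixel_size
  sapply(split(det, det$frame), function(d) {
    g <- d[d$channel == "green", ]
    r <- d[d$channel == "red", ]
    if (nrow(g) == 1 && nrow(r) == 1) {
      sqrt((g$x_px - r$x_px)^2 + (g$y_px - r$y_px)^2) * px
    } else NA_real_
  }) |> stats::na.omit() |> as.numeric()
}

# Per-detection cell-frame errors against the nearest ground-truth locus of
# the same cell/channel/frame (horizontal rendering keeps pole signs aligned).
localization_errors <- function(det, pop) {
  tr <- pop$tracks
  res <- lapply(seq_len(nrow(det)), function(i) {
    cand <- tr[tr$cell_id == det$cell_id[i] &
                 tr$channel == det$channel[i] &
                 tr$frame == det$frame[i], ]
    if (!nrow(cand)) return(NULL)
    dd <- sqrt((cand$x_nm - det$x_nm[i])^2 + (cand$y_nm - det$y_nm[i])^2)
    j <- which.min(dd)
    data.frame(dx = det$x_nm[i] - cand$x_nm[j],
               dy = det$y_nm[i] - cand$y_nm[j])
  })
  do.call(rbind, res)
}

rotate_pt <- function(p, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  as.numeric(R %*% p) + shift
}
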