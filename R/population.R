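#' Configuration for synthetic transconjugant populations
#'
#' Describes a population of rod-shaped cells, each carrying two labelled
#' chromosomal attB loci (red channel) and one labelled ICE (green channel),
#' together with the camera model used for rendering. Cell-frame coordinates
#' are `y` (longitudinal, nm, zero at the cell centre) and `x` (transversal,
#' nm, zero on the centerline).
#'
#' Class-specific motion defaults (documented in the methods vignette; the
#' underlying study reports the behaviour classes qualitatively):
#' `integrated` ICEs ride on an attB trajectory plus a ~200 nm tether;
#' `mobile_fast` ICEs are high-mobility FBM spanning most of the cell;
#' `mobile_local` ICEs are intermediate-mobility FBM confined near mid-cell;
#' `trapped` ICEs are low-mobility FBM (radius of gyration < 150 nm) placed
#' away from attB.
#'
#' @param n_cells number of cells.
#' @param class_fractions named fractions over
#'   `c("integrated", "mobile_fast", "mobile_local", "trapped")`, summing
#'   to 1.
#' @param cell_length_mean,cell_length_sd cell length distribution, nm.
#' @param cell_width cell width, nm.
#' @param attB_longitudinal_positions attB sites as fractions of cell length.
#' @param tether_distance mean ICE-attB offset for integrated cells, nm.
#' @param tether_jitter_sd per-axis fluctuation of the tether offset, nm.
#' @param dt frame interval, s.
#' @param n_frames frames per movie.
#' @param pixel_size camera pixel size, nm.
#' @param psf_sigma point-spread-function sigma, nm.
#' @param photon_budget expected photons per spot per frame.
#' @param read_noise camera read noise, counts RMS.
#' @param background mean background photons per pixel.
#' @param loc_noise_nm per-axis localization noise added when ground-truth
#'   trajectories are used directly (bypassing rendering), nm.
#' @param attB_alpha_y,attB_alpha_x,attB_D_y,attB_D_x attB motion parameters
#'   (anisotropic FBM), exponents unitless, D in nm^2/s^alpha.
#' @param mobile_fast_D,mobile_local_D,trapped_D per-axis apparent diffusion
#'   coefficients of the ICE classes, nm^2/s^alpha.
#' @param mobile_fast_alpha,mobile_local_alpha,trapped_alpha ICE class
#'   exponents.
#' @param local_halfwidth half-width of the mid-cell confinement of
#'   `mobile_local` ICEs, nm.
#' @param boundary_margin clearance kept between trajectories and the cell
#'   outline, nm.
#' @param seed master seed.
#' @return object of class `population_config`.
#' @export
population_config <- function(
    n_cells = 100L,
    class_fractions = c(integrated = 0.50, mobile_fast = 0.14,
                        mobile_local = 0.31, trapped = 0.05),
    cell_length_mean = 3000, cell_length_sd = 300, cell_width = 900,
    attB_longitudinal_positions = c(0.25, 0.75),
    tether_distance = 200, tether_jitter_sd = 25,
    dt = 4.23, n_frames = 90L,
    pixel_size = 109.76, psf_sigma = 130,
    photon_budget = 2000, read_noise = 2, background = 100,
    loc_noise_nm = 20,
    attB_alpha_y = 0.426, attB_alpha_x = 0.247,
    attB_D_y = 2500, attB_D_x = 1200,
    mobile_fast_alpha = 0.6, mobile_fast_D = 5e4,
    mobile_local_alpha = 0.5, mobile_local_D = 1.5e4,
    trapped_alpha = 0.4, trapped_D = 300,
    local_halfwidth = 300, boundary_margin = 80,
    seed = 1L) {
  labels <- c("integrated", "mobile_fast", "mobile_local", "trapped")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% labels)) {
    stop("class_fractions must be named with the behaviour labels")
  }
  fr <- setNames(numeric(4), labels)
  fr[names(class_fractions)] <- class_fractions
  if (abs(sum(fr) - 1) > 1e-9) stop("class fractions must sum to 1")
  stopifnot(
    all(attB_longitudinal_positions > 0),
    all(attB_longitudinal_positions < 1),
    cell_length_mean > cell_width, dt > 0, n_frames >= 2
  )
  structure(
    list(n_cells = as.integer(n_cells), class_fractions = fr,
         cell_length_mean = cell_length_mean,
         cell_length_sd = cell_length_sd, cell_width = cell_width,
         attB_longitudinal_positions = attB_longitudinal_positions,
         tether_distance = tether_distance,
         tether_jitter_sd = tether_jitter_sd,
         dt = dt, n_frames = as.integer(n_frames),
         pixel_size = pixel_size, psf_sigma = psf_sigma,
         photon_budget = photon_budget, read_noise = read_noise,
         background = background, loc_noise_nm = loc_noise_nm,
         attB_alpha_y = attB_alpha_y, attB_alpha_x = attB_alpha_x,
         attB_D_y = attB_D_y, attB_D_x = attB_D_x,
         mobile_fast_alpha = mobile_fast_alpha, mobile_fast_D = mobile_fast_D,
         mobile_local_alpha = mobile_local_alpha,
         mobile_local_D = mobile_local_D,
         trapped_alpha = trapped_alpha, trapped_D = trapped_D,
         local_halfwidth = local_halfwidth,
         boundary_margin = boundary_margin,
         seed = as.integer(seed)),
    class = "population_config"
  )
}

# Fold positions into [lo, hi] by reflection at the boundaries.
.reflect <- function(z, lo, hi) {
  w <- hi - lo
  if (w <= 0) stop("degenerate reflection interval")
  z <- (z - lo) %% (2 * w)
  lo + ifelse(z > w, 2 * w - z, z)
}

# One FBM path reflected into [lo, hi], starting at z0.
.fbm_confined <- function(alpha, D, dt, n, z0, lo, hi) {
  z <- z0 + c(0, cumsum(simulate_fgn_axis(alpha, D, dt, n)))
  .reflect(z, lo, hi)
}

#' Simulate a transconjugant population with known behaviour classes
#'
#' Draws `n_cells` cells; each contains two attB trajectories (anisotropic
#' FBM centred at the configured longitudinal fractions) and one ICE
#' trajectory generated according to a behaviour label drawn from the
#' configured mixture. All positions are reflected into the cell interior
#' (minus a safety margin). With `add_noise = TRUE`, independent Gaussian
#' localization noise of `loc_noise_nm` per axis is added to the reported
#' (but not the true) positions, emulating the measurement chain without
#' rendering images.
#'
#' @param cfg a [population_config()].
#' @param add_noise add localization noise to the output positions.
#' @param seed optional override of `cfg$seed`.
#' @return object of class `ground_truth`: `$cells` (per-cell geometry,
#'   label, generating parameters), `$tracks` (long table: `cell_id`,
#'   `locus_id`, `channel`, `frame`, `time_s`, `x_nm`, `y_nm`, `label`), and
#'   the config.
#' @export
simulate_population <- function(cfg, add_noise = TRUE, seed = NULL) {
  stopifnot(inherits(cfg, "population_config"))
  if (is.null(seed)) seed <- cfg$seed
  labels <- names(cfg$class_fractions)
  n <- cfg$n_cells
  nf <- cfg$n_frames
  m <- cfg$boundary_margin
  # deterministic label sequence honouring the mixture as exactly as possible
  counts <- floor(cfg$class_fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(cfg$class_fractions * n - counts, decreasing = TRUE)
    counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1
  }
  lab_seq <- rep(labels, counts)
  cells <- vector("list", n)
  tracks <- vector("list", n)
  with_seed(sub_seed(seed, 0L), {
    lab_seq <- sample(lab_seq)
    Ls <- pmax(cfg$cell_length_mean +
                 stats::rnorm(n, sd = cfg$cell_length_sd),
               cfg$cell_width * 2 + 400)
  })
  for (i in seq_len(n)) {
    L <- Ls[i]
    w <- cfg$cell_width
    lab <- lab_seq[i]
    si <- sub_seed(seed, i)
    cell_tracks <- with_seed(si, {
      ylim <- c(-L / 2 + m, L / 2 - m)
      xlim <- c(-w / 2 + m, w / 2 - m)
      attb <- lapply(seq_along(cfg$attB_longitudinal_positions), function(j) {
        y0 <- (cfg$attB_longitudinal_positions[j] - 0.5) * L
        data.frame(
          locus_id = paste0("attB", j), channel = "red",
          frame = 0:(nf - 1), time_s = (0:(nf - 1)) * cfg$dt,
          x_nm = .fbm_confined(cfg$attB_alpha_x, cfg$attB_D_x, cfg$dt, nf,
                               0, xlim[1], xlim[2]),
          y_nm = .fbm_confined(cfg$attB_alpha_y, cfg$attB_D_y, cfg$dt, nf,
                               y0, ylim[1], ylim[2])
        )
      })
      ice <- switch(lab,
        integrated = {
          host <- attb[[sample.int(length(attb), 1)]]
          phi <- stats::runif(1, 0, 2 * pi)
          off <- cfg$tether_distance * c(cos(phi), sin(phi))
          data.frame(
            locus_id = "ICE", channel = "green",
            frame = host$frame, time_s = host$time_s,
            x_nm = .reflect(host$x_nm + off[1] +
                              stats::rnorm(nf, sd = cfg$tether_jitter_sd),
                            xlim[1], xlim[2]),
            y_nm = .reflect(host$y_nm + off[2] +
                              stats::rnorm(nf, sd = cfg$tether_jitter_sd),
                            ylim[1], ylim[2])
          )
        },
        mobile_fast = data.frame(
          locus_id = "ICE", channel = "green",
          frame = 0:(nf - 1), time_s = (0:(nf - 1)) * cfg$dt,
          x_nm = .fbm_confined(cfg$mobile_fast_alpha, cfg$mobile_fast_D * 0.4,
                               cfg$dt, nf, 0, xlim[1], xlim[2]),
          y_nm = .fbm_confined(cfg$mobile_fast_alpha, cfg$mobile_fast_D,
                               cfg$dt, nf, 0, ylim[1], ylim[2])
        ),
        mobile_local = data.frame(
          locus_id = "ICE", channel = "green",
          frame = 0:(nf - 1), time_s = (0:(nf - 1)) * cfg$dt,
          x_nm = .fbm_confined(cfg$mobile_local_alpha, cfg$mobile_local_D,
                               cfg$dt, nf, 0, xlim[1], xlim[2]),
          y_nm = .fbm_confined(cfg$mobile_local_alpha, cfg$mobile_local_D,
                               cfg$dt, nf, 0,
                               max(ylim[1], -cfg$local_halfwidth),
                               min(ylim[2], cfg$local_halfwidth))
        ),
        trapped = {
          # placed away from the attB sites so "trapped" never mimics an
          # integrated pair
          ya <- (cfg$attB_longitudinal_positions - 0.5) * L
          cand <- stats::runif(50, ylim[1] + 50, ylim[2] - 50)
          clearance <- vapply(cand, function(y) min(abs(y - ya)), numeric(1))
          far <- cand[clearance > 600]
          y0 <- if (length(far)) far[1L] else cand[which.max(clearance)]
          x0 <- stats::runif(1, -w / 4, w / 4)
          data.frame(
            locus_id = "ICE", channel = "green",
            frame = 0:(nf - 1), time_s = (0:(nf - 1)) * cfg$dt,
            x_nm = .fbm_confined(cfg$trapped_alpha, cfg$trapped_D, cfg$dt,
                                 nf, x0, xlim[1], xlim[2]),
            y_nm = .fbm_confined(cfg$trapped_alpha, cfg$trapped_D, cfg$dt,
                                 nf, y0, ylim[1], ylim[2])
          )
        },
        stop("unknown label: ", lab)
      )
      out <- rbind(do.call(rbind, attb), ice)
      if (add_noise && cfg$loc_noise_nm > 0) {
        out$x_nm <- out$x_nm + stats::rnorm(nrow(out), sd = cfg$loc_noise_nm)
        out$y_nm <- out$y_nm + stats::rnorm(nrow(out), sd = cfg$loc_noise_nm)
      }
      out
    })
    cell_tracks <- cbind(cell_id = i, cell_tracks, label = lab)
    tracks[[i]] <- cell_tracks
    cells[[i]] <- data.frame(
      cell_id = i, length_nm = L, width_nm = w, label = lab,
      attB_alpha_y = cfg$attB_alpha_y, attB_alpha_x = cfg$attB_alpha_x,
      attB_D_y = cfg$attB_D_y, attB_D_x = cfg$attB_D_x
    )
  }
  structure(
    list(cells = do.call(rbind, cells), tracks = do.call(rbind, tracks),
         config = cfg, seed = seed, noisy = add_noise),
    class = "ground_truth"
  )
}

#' Ground truth for a two-channel tethered spot pair
#'
#' A single static cell containing one red spot at the cell centre and one
#' green spot at a fixed in-plane separation with a fresh uniform
#' orientation every frame — the construction used to calibrate how the
#' rendering + localization chain reads out the ICE-attB distance of an
#' integrated pair.
#'
#' @param n_frames number of frames.
#' @param separation true pair separation, nm.
#' @param cfg a [population_config()] supplying cell geometry and camera
#'   parameters (its mixture is ignored).
#' @param seed integer seed.
#' @return a `ground_truth` with one cell and two single-spot channels.
#' @export
simulate_tethered_pair <- function(n_frames = 100L, separation = 200,
                                   cfg = population_config(n_cells = 1L),
                                   seed = 1L) {
  stopifnot(inherits(cfg, "population_config"), n_frames >= 1,
            separation >= 0)
  nf <- as.integer(n_frames)
  L <- cfg$cell_length_mean
  w <- cfg$cell_width
  phi <- with_seed(seed, stats::runif(nf, 0, 2 * pi))
  f <- 0:(nf - 1)
  tracks <- rbind(
    data.frame(cell_id = 1L, locus_id = "attB1", channel = "red",
               frame = f, time_s = f * cfg$dt,
               x_nm = 0, y_nm = 0, label = "integrated"),
    data.frame(cell_id = 1L, locus_id = "ICE", channel = "green",
               frame = f, time_s = f * cfg$dt,
               x_nm = separation * sin(phi),
               y_nm = separation * cos(phi), label = "integrated")
  )
  # keep the pair inside the cell envelope
  tracks$x_nm <- pmin(pmax(tracks$x_nm, -w / 2 + 50), w / 2 - 50)
  structure(
    list(cells = data.frame(cell_id = 1L, length_nm = L, width_nm = w,
                            label = "integrated",
                            attB_alpha_y = NA_real_, attB_alpha_x = NA_real_,
                            attB_D_y = NA_real_, attB_D_x = NA_real_),
         tracks = tracks, config = cfg, seed = as.integer(seed),
         noisy = FALSE),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic population: %d cells, %d frames, dt = %.3g s\n",
              nrow(x$cells), x$config$n_frames, x$config$dt))
  print(table(x$cells$label))
  invisible(x)
}

#' Write a ground-truth table to CSV
#'
#' @param truth a `ground_truth` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(
    truth$tracks[, c("cell_id", "locus_id", "channel", "frame", "time_s",
                     "x_nm", "y_nm", "label")],
    path, row.names = FALSE)
  invisible(path)
}

# Split a tracks table into per-locus trajectory data.frames.
split_tracks <- function(tracks) {
  key <- interaction(tracks$cell_id, tracks$locus_id, drop = TRUE)
  lapply(split(tracks, key), function(d) d[order(d$frame), ])
}
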