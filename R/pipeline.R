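#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end pipeline. A condition
#' tag selects a synthetic parameter preset emulating the qualitative effect
#' of a treatment on locus mobility (presets only modulate generator
#' parameters; no drug mechanism is modelled):
#' \describe{
#'   \item{untreated}{population defaults.}
#'   \item{rifampicin_like}{most elements highly mobile (fast fraction 0.76)
#'     and apparent diffusion coefficients increased ~2.5-fold.}
#'   \item{chloramphenicol_like}{mobility reduced (D scaled 0.6).}
#'   \item{dnp_like}{energy-depleted: D scaled 0.3, trapped fraction
#'     increased.}
#' }
#'
#' @param condition preset tag (see above).
#' @param n_cells,n_frames,dt,seed population size, movie length, frame
#'   interval (s), master seed.
#' @param render render images and localize them (slow); otherwise the
#'   ground-truth trajectories (plus localization noise) feed the analysis
#'   directly.
#' @param frame_px rendered frame side, px.
#' @param pixel_size nm per pixel.
#' @param fit_lags MSD power-law fit range, lag indices.
#' @param deltas VACF velocity intervals, frames.
#' @param filter_step mobility filter threshold, nm.
#' @param fold pole-fold position distributions.
#' @param figures write SVG figures.
#' @param out output directory (`NULL`: nothing written, results returned
#'   only).
#' @param ... overrides passed to [population_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(condition = c("untreated", "rifampicin_like",
                                     "chloramphenicol_like", "dnp_like"),
                       n_cells = 100L, n_frames = 90L, dt = 4.23,
                       seed = 1L, render = FALSE, frame_px = 512L,
                       pixel_size = 109.76, fit_lags = 2:10,
                       deltas = c(1L, 2L, 4L, 8L), filter_step = 200,
                       fold = FALSE, figures = FALSE, out = NULL, ...) {
  condition <- match.arg(condition)
  base <- list(n_cells = n_cells, n_frames = n_frames, dt = dt,
               pixel_size = pixel_size, seed = seed)
  tweak <- switch(condition,
    untreated = list(),
    rifampicin_like = list(
      class_fractions = c(integrated = 0.10, mobile_fast = 0.76,
                          mobile_local = 0.10, trapped = 0.04),
      attB_D_y = 2500 * 2.5, attB_D_x = 1200 * 2.5,
      mobile_fast_D = 5e4 * 2.5, mobile_local_D = 1.5e4 * 2.5),
    chloramphenicol_like = list(
      attB_D_y = 2500 * 0.6, attB_D_x = 1200 * 0.6,
      mobile_fast_D = 5e4 * 0.6, mobile_local_D = 1.5e4 * 0.6),
    dnp_like = list(
      class_fractions = c(integrated = 0.30, mobile_fast = 0.05,
                          mobile_local = 0.25, trapped = 0.40),
      attB_D_y = 2500 * 0.3, attB_D_x = 1200 * 0.3,
      mobile_fast_D = 5e4 * 0.3, mobile_local_D = 1.5e4 * 0.3,
      trapped_D = 100)
  )
  pop_args <- utils::modifyList(c(base, tweak), list(...))
  pop_cfg <- do.call(population_config, pop_args)
  structure(
    list(condition = condition, population = pop_cfg, render = render,
         frame_px = as.integer(frame_px), fit_lags = fit_lags,
         deltas = as.integer(deltas), filter_step = filter_step,
         fold = fold, figures = figures, out = out, seed = as.integer(seed),
         dt = dt),
    class = "run_config"
  )
}

#' Run the full simulate-measure-analyse pipeline
#'
#' Stages: simulate a population; optionally render it to images and recover
#' trajectories by segmentation, localization and linking (otherwise the
#' noisy ground-truth trajectories are used directly); compute MSD power-law
#' fits (2D and per axis, time- and ensemble-averaged) of the attB
#' trajectories, the VACF rescaling collapse and the ergodicity verdict;
#' classify ICE behaviour; and pool longitudinal position distributions. The
#' run is deterministic given the seed. When `cfg$out` is set, intermediate
#' tables (CSV), the resolved configuration (YAML), a JSON summary, a log of
#' every threshold used, and optional SVG figures are written there.
#'
#' @param cfg a [run_config()].
#' @return the summary list, invisibly when written to disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- c(sprintf("condition: %s", cfg$condition),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("fit lags: %s", paste(range(cfg$fit_lags),
                                               collapse = "-")),
                 sprintf("VACF deltas (frames): %s",
                         paste(cfg$deltas, collapse = ",")),
                 sprintf("mobility filter: > %g nm", cfg$filter_step))
  out <- cfg$out
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pop <- simulate_population(cfg$population, add_noise = !cfg$render)
  tracks <- pop$tracks
  if (cfg$render) {
    st <- render_stack(pop, frame_px = cfg$frame_px)
    if (!is.null(out)) write_stack_tiff(st, file.path(out, "stack"))
    det <- localize_stack(st, dt = cfg$dt)
    if (!is.null(out)) {
      utils::write.csv(det, file.path(out, "detections.csv"),
                       row.names = FALSE)
    }
    tracks <- link_trajectories(det, min_len = min(20L,
                                                   cfg$population$n_frames %/% 2L))
    # rendered cell ids follow placement order = original ids
    tracks$locus_id <- paste0(tracks$channel, tracks$locus_id)
  }
  if (!is.null(out)) {
    utils::write.csv(
      tracks[, intersect(c("cell_id", "locus_id", "channel", "frame",
                           "time_s", "x_nm", "y_nm", "label"),
                         names(tracks))],
      file.path(out, "trajectories.csv"), row.names = FALSE)
  }
  attb <- split_tracks(tracks[tracks$channel == "red", ])
  dynamics <- list()
  for (comp in c("r2d", "x", "y")) {
    ta_fit <- fit_power_law(ta_msd(attb, component = comp),
                            lag_range = cfg$fit_lags)
    ea_fit <- fit_power_law(ea_msd(attb, component = comp),
                            lag_range = cfg$fit_lags)
    dynamics[[comp]] <- list(
      ta = list(D = ta_fit$D, alpha = ta_fit$alpha,
                se_alpha = ta_fit$se_alpha),
      ea = list(D = ea_fit$D, alpha = ea_fit$alpha,
                se_alpha = ea_fit$se_alpha))
  }
  erg <- ergodicity_report(attb, fit_lags = cfg$fit_lags)
  span <- min(vapply(attb, nrow, integer(1)))
  deltas <- cfg$deltas[cfg$deltas <= span / 4]
  if (length(deltas) < length(cfg$deltas)) {
    log_lines <- c(log_lines, sprintf(
      "VACF deltas reduced to {%s}: trajectories span only %d frames",
      paste(deltas, collapse = ","), span))
  }
  alpha_2d <- dynamics$r2d$ta$alpha
  vl <- lapply(deltas, function(m) vacf(attb, delta = m))
  col <- if (length(vl) >= 2) {
    rescale_collapse(vl, alpha = alpha_2d)
  } else {
    list(rms_spread = NA_real_, rms_theory = NA_real_)
  }
  dw <- walk_fractal_dimension(alpha_2d)
  # distances + classification
  dist_rows <- lapply(split(tracks, tracks$cell_id), function(ct) {
    ice <- ct[ct$channel == "green", ]
    ab <- split_tracks(ct[ct$channel == "red", ])
    if (nrow(ice) < 2 || !length(ab)) return(NULL)
    d <- tryCatch(nearest_attb_distance(ice, ab), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    cbind(cell_id = ct$cell_id[1], d)
  })
  distances <- do.call(rbind, dist_rows)
  if (!is.null(out) && !is.null(distances)) {
    utils::write.csv(distances, file.path(out, "distances.csv"),
                     row.names = FALSE)
  }
  cls <- classify_population(tracks, pop$cells)
  if (!is.null(out)) {
    utils::write.csv(cbind(cls$labels), file.path(out, "labels.csv"),
                     row.names = FALSE)
  }
  ice_trajs <- split_tracks(tracks[tracks$channel == "green", ])
  ice_mobile <- mobility_filter(ice_trajs, step_nm = cfg$filter_step)
  pd_ice <- if (length(ice_mobile)) {
    position_distribution(ice_mobile, pop$cells, fold = cfg$fold)
  } else NULL
  pd_attb <- position_distribution(attb, pop$cells, fold = cfg$fold)
  summary <- list(
    condition = cfg$condition, seed = cfg$seed,
    n_cells = nrow(pop$cells), n_frames = cfg$population$n_frames,
    dt = cfg$dt, dynamics = dynamics,
    walk_dimension = dw$d_w, compact_exploration = dw$compact,
    ergodicity = list(verdict = erg$verdict,
                      delta_alpha = erg$delta_alpha,
                      se = erg$se_delta_alpha),
    vacf_collapse = list(rms_spread = col$rms_spread,
                         rms_theory = col$rms_theory),
    class_fractions = cls$fractions,
    attb_peaks = head(pd_attb$peaks, 2),
    ice_peak = if (!is.null(pd_ice)) head(pd_ice$peaks, 1) else NA_real_,
    mobile_kept = length(ice_mobile), mobile_total = length(ice_trajs)
  )
  if (!is.null(out)) {
    yaml::write_yaml(.serialize_config(cfg), file.path(out, "config.yaml"))
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out, "run.log"))
    if (cfg$figures) {
      grDevices::svg(file.path(out, "msd.svg"), width = 6, height = 5)
      plot(ta_msd(attb), fit = fit_power_law(ta_msd(attb),
                                             lag_range = cfg$fit_lags),
           main = "attB time-averaged MSD")
      grDevices::dev.off()
      grDevices::svg(file.path(out, "vacf_collapse.svg"), width = 6,
                     height = 5)
      plot(col, main = "VACF rescaling collapse")
      grDevices::dev.off()
      grDevices::svg(file.path(out, "positions.svg"), width = 6, height = 5)
      plot(pd_attb, main = "attB longitudinal positions")
      grDevices::dev.off()
    }
    return(invisible(summary))
  }
  summary
}

# Flatten a run_config for lossless YAML round-tripping.
.serialize_config <- function(cfg) {
  pc <- unclass(cfg$population)
  pc$class_fractions <- as.list(pc$class_fractions)
  list(condition = cfg$condition, seed = cfg$seed, render = cfg$render,
       frame_px = cfg$frame_px, fit_lags = as.integer(cfg$fit_lags),
       deltas = as.integer(cfg$deltas), filter_step = cfg$filter_step,
       fold = cfg$fold, figures = cfg$figures, dt = cfg$dt,
       population = pc)
}

#' Rebuild a run configuration from a serialized YAML file
#'
#' @param path YAML written by [run_pipeline()] (or hand-edited).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pop <- y$population
  run_config(
    condition = y$condition, n_cells = pop$n_cells,
    n_frames = pop$n_frames, dt = y$dt, seed = y$seed, render = y$render,
    frame_px = y$frame_px, fit_lags = y$fit_lags[1]:y$fit_lags[length(y$fit_lags)],
    deltas = y$deltas, filter_step = y$filter_step, fold = y$fold,
    figures = y$figures,
    class_fractions = unlist(pop$class_fractions),
    cell_length_mean = pop$cell_length_mean,
    cell_length_sd = pop$cell_length_sd, cell_width = pop$cell_width,
    attB_longitudinal_positions = pop$attB_longitudinal_positions,
    tether_distance = pop$tether_distance,
    pixel_size = pop$pixel_size, psf_sigma = pop$psf_sigma,
    photon_budget = pop$photon_budget, read_noise = pop$read_noise,
    background = pop$background, loc_noise_nm = pop$loc_noise_nm
  )
}
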