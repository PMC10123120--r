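#' Render a synthetic population as a two-channel fluorescence stack
#'
#' Produces, per frame, a phase-contrast-like channel (dark stadium-shaped
#' cells on a bright background with Gaussian noise), a green channel (ICE
#' spots) and a red channel (attB spots). Each spot is rendered as a
#' pixel-integrated symmetric 2D Gaussian of width `psf_sigma`, scaled to
#' `photon_budget` photons; the camera model is Poisson(signal + background)
#' shot noise plus Gaussian read noise. Rendering is deterministic given the
#' seed.
#'
#' Cells are laid out on a grid, horizontal by default or at per-cell random
#' orientations (`random_orientation`); cells that cannot be placed without
#' touching the frame edge are rejected with a warning. Pixel convention:
#' 0-based indices with the pixel center at integer coordinates; the lab
#' position of a locus is `cell center + R(theta) %*% c(y_cell, x_cell)`.
#'
#' @param truth a `ground_truth` from [simulate_population()] (its noise-free
#'   positions are rendered, regardless of `add_noise`).
#' @param frame_px frame side, pixels (default 512).
#' @param frames which frames to render (default all).
#' @param cells which cell ids to render (default as many as fit).
#' @param random_orientation draw a uniform orientation per cell instead of
#'   horizontal placement.
#' @param noise render shot and read noise (`FALSE` gives the noiseless
#'   expected image, the localization-bias oracle).
#' @param seed seed for the camera noise; defaults to the truth's seed.
#' @return object of class `rendered_stack`: `phase`, `green`, `red` (arrays
#'   `[row, col, frame]`, photons/counts), `placement` (per-cell lab-frame
#'   center px and orientation), `truth_px` (per spot per frame: lab-frame px
#'   plus the originating cell-frame nm), `pixel_size`, and the camera
#'   parameters used.
#' @export
render_stack <- function(truth, frame_px = 512L, frames = NULL, cells = NULL,
                         random_orientation = FALSE, noise = TRUE,
                         seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  px <- cfg$pixel_size
  if (is.null(seed)) seed <- sub_seed(truth$seed, 9999L)
  if (is.null(frames)) frames <- sort(unique(truth$tracks$frame))
  all_cells <- truth$cells
  # grid layout: cell pitch from the largest cell, margin from its half-diagonal
  pitch_nm <- max(all_cells$length_nm) + 2 * max(all_cells$width_nm)
  pitch <- ceiling(pitch_nm / px)
  margin <- ceiling(pitch / 2) + 2L
  per_row <- max(1L, floor((frame_px - 2L * margin) / pitch) + 1L)
  n_rows <- max(1L, floor((frame_px - 2L * margin) / pitch) + 1L)
  capacity <- per_row * n_rows
  if (is.null(cells)) cells <- all_cells$cell_id
  if (length(cells) > capacity) {
    warning(sprintf("frame holds %d cells; rendering the first %d of %d",
                    capacity, capacity, length(cells)))
    cells <- cells[seq_len(capacity)]
  }
  placement <- with_seed(sub_seed(seed, 1L), {
    idx <- seq_along(cells) - 1L
    data.frame(
      cell_id = cells,
      cx_px = margin + (idx %% per_row) * pitch,
      cy_px = margin + (idx %/% per_row) * pitch,
      theta = if (random_orientation) {
        stats::runif(length(cells), 0, pi)
      } else rep(0, length(cells))
    )
  })
  geom <- all_cells[match(cells, all_cells$cell_id), ]
  # lab-frame spot positions (px) for every track row of the rendered cells
  tr <- truth$tracks[truth$tracks$cell_id %in% cells &
                       truth$tracks$frame %in% frames, ]
  pi_ <- match(tr$cell_id, placement$cell_id)
  th <- placement$theta[pi_]
  # cell frame: y = longitudinal, x = transversal; lab axes in nm then px
  lab_dx <- cos(th) * tr$y_nm - sin(th) * tr$x_nm
  lab_dy <- sin(th) * tr$y_nm + cos(th) * tr$x_nm
  tr$x_px <- placement$cx_px[pi_] + lab_dx / px
  tr$y_px <- placement$cy_px[pi_] + lab_dy / px
  H <- W <- as.integer(frame_px)
  sig_px <- cfg$psf_sigma / px
  # phase channel template (static): bright background, dark stadiums
  xg <- matrix(rep(0:(W - 1L), each = H), H, W)   # x = column index
  yg <- matrix(rep(0:(H - 1L), times = W), H, W)  # y = row index
  phase_t <- matrix(0.8, H, W)
  for (k in seq_len(nrow(placement))) {
    L_px <- geom$length_nm[k] / px
    w_px <- geom$width_nm[k] / px
    hl <- pmax(L_px / 2 - w_px / 2, 0.5) # half-length of the core segment
    ux <- cos(placement$theta[k]); uy <- sin(placement$theta[k])
    rx <- xg - placement$cx_px[k]
    ry <- yg - placement$cy_px[k]
    s <- pmin(pmax(rx * ux + ry * uy, -hl), hl) # clamp to segment
    d2 <- (rx - s * ux)^2 + (ry - s * uy)^2
    phase_t[d2 <= (w_px / 2)^2] <- 0.3
  }
  nfr <- length(frames)
  phase <- array(0, c(H, W, nfr))
  green <- array(0, c(H, W, nfr))
  red <- array(0, c(H, W, nfr))
  with_seed(sub_seed(seed, 2L), {
    for (fi in seq_len(nfr)) {
      f <- frames[fi]
      sub <- tr[tr$frame == f, ]
      for (ch in c("green", "red")) {
        img <- matrix(cfg$background, H, W)
        sp <- sub[sub$channel == ch, ]
        for (si in seq_len(nrow(sp))) {
          img <- .add_spot(img, sp$x_px[si], sp$y_px[si], sig_px,
                           cfg$photon_budget)
        }
        if (noise) {
          img <- matrix(stats::rpois(H * W, img), H, W) +
            matrix(stats::rnorm(H * W, sd = cfg$read_noise), H, W)
        }
        if (ch == "green") green[, , fi] <- img else red[, , fi] <- img
      }
      phase[, , fi] <- phase_t +
        if (noise) matrix(stats::rnorm(H * W, sd = 0.02), H, W) else 0
    }
  })
  structure(
    list(phase = phase, green = green, red = red,
         frames = frames, placement = placement, truth_px = tr,
         pixel_size = px, psf_sigma = cfg$psf_sigma,
         photon_budget = cfg$photon_budget, read_noise = cfg$read_noise,
         background = cfg$background, noise = noise),
    class = "rendered_stack"
  )
}

# Add one pixel-integrated Gaussian spot (total flux = photons) to an image.
# 0-based pixel centers at integers; pixel (x, y) spans [x - .5, x + .5].
.add_spot <- function(img, x0, y0, sigma_px, photons) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(4 * sigma_px)
  xs <- max(0L, floor(x0) - r):min(W - 1L, ceiling(x0) + r)
  ys <- max(0L, floor(y0) - r):min(H - 1L, ceiling(y0) + r)
  if (!length(xs) || !length(ys)) return(img)
  fx <- stats::pnorm(xs + 0.5, x0, sigma_px) - stats::pnorm(xs - 0.5, x0, sigma_px)
  fy <- stats::pnorm(ys + 0.5, y0, sigma_px) - stats::pnorm(ys - 0.5, y0, sigma_px)
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + photons * outer(fy, fx)
  img
}

#' @export
print.rendered_stack <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(
    "Rendered stack: %d x %d px, %d frames, %d cells, %.4g nm/px%s\n",
    d[1], d[2], d[3], nrow(x$placement), x$pixel_size,
    if (x$noise) "" else " (noiseless)"))
  invisible(x)
}

#' Write a rendered stack to multi-page TIFF files
#'
#' One 32-bit float multi-page TIFF per channel (`phase.tif`, `green.tif`,
#' `red.tif`); sample values are normalized to `[0, 1]` by the channel
#' maximum, which is recorded in a `scales.csv` sidecar so counts can be
#' restored on read. The lab-frame truth table is written as CSV.
#'
#' @param stack a `rendered_stack`.
#' @param dir output directory (created if needed).
#' @return named vector of the files written, invisibly.
#' @export
write_stack_tiff <- function(stack, dir) {
  stopifnot(inherits(stack, "rendered_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(phase = file.path(dir, "phase.tif"),
             green = file.path(dir, "green.tif"),
             red = file.path(dir, "red.tif"),
             scales = file.path(dir, "scales.csv"),
             truth = file.path(dir, "truth.csv"))
  scales <- c(phase = NA_real_, green = NA_real_, red = NA_real_)
  for (ch in c("phase", "green", "red")) {
    a <- stack[[ch]]
    lo <- min(a, 0)
    sc <- max(a - lo)
    if (sc <= 0) sc <- 1
    scales[ch] <- sc
    pages <- lapply(seq_len(dim(a)[3]), function(i) (a[, , i] - lo) / sc)
    tiff::writeTIFF(pages, files[[ch]], bits.per.sample = 32L,
                    reduce = FALSE)
  }
  utils::write.csv(data.frame(channel = names(scales), scale = scales),
                   files[["scales"]], row.names = FALSE)
  tt <- stack$truth_px
  utils::write.csv(
    tt[, c("cell_id", "locus_id", "channel", "frame", "time_s",
           "x_nm", "y_nm", "x_px", "y_px", "label")],
    files[["truth"]], row.names = FALSE)
  invisible(files)
}

#' Read a multi-page TIFF into an array
#'
#' @param path TIFF file.
#' @return numeric array `[row, col, frame]`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    arr[, , i] <- p
  }
  arr
}
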