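#' Segment rod-shaped cells in a phase-contrast-like image
#'
#' Cells are dark objects on a bright background. The image is thresholded
#' (Otsu), closed morphologically, hole-filled and labelled; components
#' touching the frame border or smaller than `min_area` are discarded. For
#' each remaining cell the geometry is extracted: center of mass, a
#' centerline (transverse midpoints binned along the principal axis, median
#' smoothed), arc-length cell length, and a transverse-extent width.
#'
#' @param img numeric matrix (`[row, col]`, 0-based pixel centers at integer
#'   coordinates: `x = col - 1`, `y = row - 1`).
#' @param pixel_size nm per pixel.
#' @param min_area minimum component area, px.
#' @param invert set `FALSE` when cells are bright instead of dark.
#' @return list of `cell_geometry` objects (possibly empty, with a warning):
#'   each has `id`, `mask` (logical matrix), `area_px`, `com_px` (x, y),
#'   `centerline_px` (ordered x, y matrix), `com_arc_px` (arc-length position
#'   of the center-of-mass projection), `length_nm`, `width_nm`,
#'   `boundary_px`, `pole_u` (unit vector along the centerline fixing pole
#'   identity).
#' @export
segment_cells <- function(img, pixel_size = 109.76, min_area = 40L,
                          invert = TRUE) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  norm <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  if (invert) norm <- 1 - norm
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > th
  ker <- EBImage::makeBrush(3, shape = "box")
  bw <- EBImage::closing(EBImage::Image(bw * 1), ker)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  if (nlab == 0) {
    warning("no cells found")
    return(list())
  }
  H <- nrow(img); W <- ncol(img)
  border_ids <- unique(c(labm[1, ], labm[H, ], labm[, 1], labm[, W]))
  out <- list()
  for (id in seq_len(nlab)) {
    if (id %in% border_ids) next
    mask <- labm == id
    if (sum(mask) < min_area) next
    g <- .geom_from_mask(mask, pixel_size, id = length(out) + 1L)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  if (!length(out)) warning("no cells found away from the frame border")
  out
}

# Build a cell_geometry from a logical mask.
.geom_from_mask <- function(mask, pixel_size, id = 1L) {
  pix <- which(mask, arr.ind = TRUE)
  x <- pix[, 2L] - 1
  y <- pix[, 1L] - 1
  com <- c(mean(x), mean(y))
  cv <- stats::cov(cbind(x, y))
  eg <- eigen(cv, symmetric = TRUE)
  u <- eg$vectors[, 1L]
  # fix pole identity: major-axis direction points toward positive x
  # (or positive y for near-vertical cells)
  if (abs(u[1]) >= abs(u[2])) {
    if (u[1] < 0) u <- -u
  } else if (u[2] < 0) u <- -u
  v <- c(-u[2], u[1]) # left-hand normal
  s <- (x - com[1]) * u[1] + (y - com[2]) * u[2]
  t <- (x - com[1]) * v[1] + (y - com[2]) * v[2]
  sbin <- round(s)
  agg_mid <- tapply(t, sbin, function(z) (min(z) + max(z)) / 2)
  agg_ext <- tapply(t, sbin, function(z) max(z) - min(z) + 1)
  sb <- as.numeric(names(agg_mid))
  o <- order(sb)
  sb <- sb[o]
  mid <- as.numeric(agg_mid)[o]
  ext <- as.numeric(agg_ext)[o]
  if (length(sb) < 3) return(NULL)
  if (length(mid) >= 5) mid <- stats::runmed(mid, 5)
  cl <- cbind(x = com[1] + sb * u[1] + mid * v[1],
              y = com[2] + sb * u[2] + mid * v[2])
  seg <- sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)
  arc <- c(0, cumsum(seg))
  core <- ext[sb > min(sb) + 2 & sb < max(sb) - 2]
  width_px <- if (length(core)) stats::median(core) else stats::median(ext)
  com_arc <- .project_polyline(cl, arc, com)$arc
  boundary <- tryCatch({
    oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
    cbind(x = oc[, 1L] - 1, y = oc[, 2L] - 1)
  }, error = function(e) NULL)
  structure(
    list(id = id, mask = mask, area_px = nrow(pix), com_px = com,
         centerline_px = cl, arc_px = arc, com_arc_px = com_arc,
         length_nm = sum(seg) * pixel_size + pixel_size, # tip-to-tip
         width_nm = width_px * pixel_size,
         boundary_px = boundary, pole_u = u, pixel_size = pixel_size),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "Cell %d: L = %.0f nm, w = %.0f nm, COM (%.1f, %.1f) px, %d px area\n",
    x$id, x$length_nm, x$width_nm, x$com_px[1], x$com_px[2], x$area_px))
  invisible(x)
}

# Nearest point on a polyline: foot coordinates, arc-length position, signed
# transverse offset (positive to the left of the running direction), and
# whether the projection had to be clamped to an endpoint.
.project_polyline <- function(cl, arc, p) {
  n <- nrow(cl)
  best <- list(d2 = Inf)
  for (i in seq_len(n - 1L)) {
    a <- cl[i, ]; b <- cl[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    tt <- sum((p - a) * ab) / len2
    tc <- min(max(tt, 0), 1)
    foot <- a + tc * ab
    d2 <- sum((p - foot)^2)
    if (d2 < best$d2 - 1e-12) {
      dirn <- ab / sqrt(len2)
      cross_z <- dirn[1] * (p[2] - foot[2]) - dirn[2] * (p[1] - foot[1])
      best <- list(
        d2 = d2, arc = arc[i] + tc * sqrt(len2),
        perp = sign(ifelse(cross_z == 0, 1, cross_z)) * sqrt(d2),
        clamped = (i == 1L && tt < 0) || (i == n - 1L && tt > 1)
      )
    }
  }
  best
}

#' Detect candidate spots inside one cell
#'
#' Pixels of a fluorescence image above a per-cell robust threshold (median
#' plus `threshold_k` MADs of the in-mask background, or an absolute value)
#' are grouped into connected clusters within the cell mask; each cluster is
#' reduced to its brightest pixel, the seed for the sub-pixel fit. Clusters
#' larger than a quarter of the cell area are rejected as artifacts.
#'
#' @param img fluorescence image matrix (same frame as the geometry).
#' @param geom a `cell_geometry`.
#' @param threshold_k MAD multiplier (default 5).
#' @param threshold_abs absolute intensity threshold overriding the robust
#'   rule.
#' @return data.frame `x_px`, `y_px` (0-based seed pixel), `peak`,
#'   `cluster_px`, ordered by decreasing peak intensity.
#' @export
detect_spots <- function(img, geom, threshold_k = 5, threshold_abs = NULL) {
  stopifnot(is.matrix(img), inherits(geom, "cell_geometry"),
            all(dim(img) == dim(geom$mask)))
  vals <- img[geom$mask]
  thr <- if (!is.null(threshold_abs)) threshold_abs else {
    spread <- stats::mad(vals)
    # MAD degenerates on noise-free synthetic input; fall back to the SD
    if (spread <= 0) spread <- max(stats::sd(vals), .Machine$double.eps)
    stats::median(vals) + threshold_k * spread
  }
  above <- img > thr & geom$mask
  if (!any(above)) {
    return(data.frame(x_px = integer(0), y_px = integer(0),
                      peak = numeric(0), cluster_px = integer(0)))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(above * 1)))
  rows <- lapply(seq_len(max(lab)), function(id) {
    pp <- which(lab == id, arr.ind = TRUE)
    if (nrow(pp) > geom$area_px / 4) return(NULL) # artifact
    iv <- img[pp]
    top <- which.max(iv)
    data.frame(x_px = pp[top, 2L] - 1L, y_px = pp[top, 1L] - 1L,
               peak = iv[top], cluster_px = nrow(pp))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(x_px = integer(0), y_px = integer(0),
                      peak = numeric(0), cluster_px = integer(0)))
  }
  out[order(-out$peak), , drop = FALSE]
}

#' Sub-pixel Gaussian-plus-constant spot fit
#'
#' Nonlinear least squares of
#' `I(p) = A * exp(-((px - x0)^2 + (py - y0)^2) / (2 sigma^2)) + B`
#' over a square window centered on the seed pixel (shifted inward at frame
#' edges). Fits that fail to converge or end on the sigma bounds are
#' rejected (`NULL`).
#'
#' @param img image matrix.
#' @param seed_xy seed pixel `c(x, y)`, 0-based.
#' @param window window side, px (odd, default 7).
#' @param sigma_bounds allowed sigma range, px.
#' @return list `x0`, `y0` (sub-pixel, 0-based), `amplitude`, `sigma_px`,
#'   `offset`, `residual` (RMS), or `NULL` if rejected.
#' @export
fit_spot_gaussian <- function(img, seed_xy, window = 7L,
                              sigma_bounds = c(0.5, 5)) {
  H <- nrow(img); W <- ncol(img)
  hw <- window %/% 2L
  cx <- min(max(round(seed_xy[1]), hw), W - 1L - hw)
  cy <- min(max(round(seed_xy[2]), hw), H - 1L - hw)
  xs <- (cx - hw):(cx + hw)
  ys <- (cy - hw):(cy + hw)
  win <- img[ys + 1L, xs + 1L]
  d <- data.frame(
    I = as.vector(win),
    px = rep(xs, each = length(ys)),
    py = rep(ys, times = length(xs))
  )
  start <- list(A = max(d$I) - min(d$I), x0 = seed_xy[1], y0 = seed_xy[2],
                s = 1.2, B = min(d$I))
  if (start$A <= 0) return(NULL)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ A * exp(-((px - x0)^2 + (py - y0)^2) / (2 * s^2)) + B,
      data = d, start = start,
      lower = c(A = 1e-9, x0 = min(xs) - 1, y0 = min(ys) - 1,
                s = sigma_bounds[1], B = -Inf),
      upper = c(A = Inf, x0 = max(xs) + 1, y0 = max(ys) + 1,
                s = sigma_bounds[2], B = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  eps <- 1e-6
  if (cf["s"] <= sigma_bounds[1] + eps || cf["s"] >= sigma_bounds[2] - eps) {
    return(NULL)
  }
  list(x0 = unname(cf["x0"]), y0 = unname(cf["y0"]),
       amplitude = unname(cf["A"]), sigma_px = unname(cf["s"]),
       offset = unname(cf["B"]),
       residual = sqrt(mean(stats::residuals(fit)^2)))
}

#' Convert a lab-frame spot position to cell-frame coordinates
#'
#' `x` is the signed perpendicular distance (nm) from the spot to the
#' nearest centerline segment (transversal axis); `y` is the arc-length
#' position (nm) along the centerline of the projection foot point, measured
#' from the projection of the cell's center of mass (longitudinal axis).
#' Signs follow the cell's frozen pole orientation (`pole_u`), so they stay
#' consistent over a movie. Projections falling beyond the centerline ends
#' are clamped and flagged.
#'
#' @param spot_xy lab-frame position `c(x, y)`, px (sub-pixel).
#' @param geom a `cell_geometry`.
#' @param pixel_size nm per pixel (defaults to the geometry's).
#' @return list `x_nm`, `y_nm`, `clamped`.
#' @export
to_cell_frame <- function(spot_xy, geom, pixel_size = NULL) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (is.null(pixel_size)) pixel_size <- geom$pixel_size
  pr <- .project_polyline(geom$centerline_px, geom$arc_px, spot_xy)
  list(x_nm = unname(pr$perp) * pixel_size,
       y_nm = unname(pr$arc - geom$com_arc_px) * pixel_size,
       clamped = unname(pr$clamped))
}

#' Localize spots in a rendered (or loaded) stack
#'
#' Full per-frame localization: segment the phase channel, match cells to
#' the first frame (nearest center of mass, frozen pole orientation), detect
#' and fit spots per fluorescence channel, convert to cell-frame nm. At most
#' `max_spots` spots per channel per cell are accepted; frames where a cell
#' shows more are dropped for that channel (counted in the attrition
#' summary).
#'
#' @param stack a `rendered_stack`, or a named list of arrays
#'   `list(phase =, green =, red =)` (`[row, col, frame]`).
#' @param pixel_size nm per pixel (taken from a `rendered_stack`).
#' @param dt frame interval, s, used for the `time_s` column.
#' @param threshold_k spot-detection MAD multiplier.
#' @param window Gaussian fit window, px.
#' @param max_spots maximum spots accepted per channel per cell.
#' @param channels which fluorescence channels to process.
#' @return data.frame `cell_id`, `channel`, `frame`, `time_s`, `x_px`,
#'   `y_px` (lab, sub-pixel), `x_nm`, `y_nm` (cell frame), `amplitude`,
#'   `sigma_px`, `offset`, `residual`, `clamped`; the attrition summary is
#'   attached as attribute `"dropped"`.
#' @export
localize_stack <- function(stack, pixel_size = NULL, dt = 4.23,
                           threshold_k = 5, window = 7L, max_spots = 2L,
                           channels = c("green", "red")) {
  if (inherits(stack, "rendered_stack")) {
    if (is.null(pixel_size)) pixel_size <- stack$pixel_size
    arrs <- list(phase = stack$phase, green = stack$green, red = stack$red)
    frames <- stack$frames
  } else {
    stopifnot(is.list(stack), "phase" %in% names(stack))
    if (is.null(pixel_size)) stop("pixel_size required for raw arrays")
    arrs <- stack
    frames <- seq_len(dim(stack$phase)[3]) - 1L
  }
  nfr <- length(frames)
  ref <- NULL
  out <- vector("list", nfr)
  dropped <- c(multi_spot = 0L, failed_fit = 0L, unmatched_cell = 0L)
  for (fi in seq_len(nfr)) {
    geoms <- segment_cells(arrs$phase[, , fi], pixel_size)
    if (!length(geoms)) next
    if (is.null(ref)) {
      ref <- geoms
      ref_com <- t(vapply(ref, `[[`, numeric(2), "com_px"))
    } else {
      # match to first-frame cells; freeze pole orientation
      matched <- vector("list", length(ref))
      for (g in geoms) {
        dd <- sqrt((ref_com[, 1] - g$com_px[1])^2 +
                     (ref_com[, 2] - g$com_px[2])^2)
        j <- which.min(dd)
        if (dd[j] < max(g$width_nm / pixel_size, 5)) {
          if (sum(g$pole_u * ref[[j]]$pole_u) < 0) {
            g$centerline_px <- g$centerline_px[rev(seq_len(nrow(g$centerline_px))), ]
            g$arc_px <- max(g$arc_px) - rev(g$arc_px)
            g$com_arc_px <- .project_polyline(g$centerline_px, g$arc_px,
                                              g$com_px)$arc
            g$pole_u <- -g$pole_u
          }
          g$id <- ref[[j]]$id
          matched[[j]] <- g
        } else {
          dropped["unmatched_cell"] <- dropped["unmatched_cell"] + 1L
        }
      }
      geoms <- Filter(Negate(is.null), matched)
    }
    rows <- list()
    for (g in geoms) {
      for (ch in channels) {
        img <- arrs[[ch]][, , fi]
        det <- detect_spots(img, g, threshold_k = threshold_k)
        if (nrow(det) > max_spots) {
          dropped["multi_spot"] <- dropped["multi_spot"] + 1L
          next
        }
        for (si in seq_len(nrow(det))) {
          ft <- fit_spot_gaussian(img, c(det$x_px[si], det$y_px[si]),
                                  window = window)
          if (is.null(ft)) {
            dropped["failed_fit"] <- dropped["failed_fit"] + 1L
            next
          }
          cfr <- to_cell_frame(c(ft$x0, ft$y0), g, pixel_size)
          rows[[length(rows) + 1L]] <- data.frame(
            cell_id = g$id, channel = ch, frame = frames[fi],
            time_s = frames[fi] * dt, x_px = ft$x0, y_px = ft$y0,
            x_nm = cfr$x_nm, y_nm = cfr$y_nm,
            amplitude = ft$amplitude, sigma_px = ft$sigma_px,
            offset = ft$offset, residual = ft$residual,
            clamped = cfr$clamped)
        }
      }
    }
    out[[fi]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cell_id = integer(0), channel = character(0),
                      frame = integer(0), time_s = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      amplitude = numeric(0), sigma_px = numeric(0),
                      offset = numeric(0), residual = numeric(0),
                      clamped = logical(0))
  }
  attr(res, "dropped") <- dropped
  res
}
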