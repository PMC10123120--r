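#' Classify the behaviour of one ICE trajectory
#'
#' Decision cascade over explicit, configurable thresholds (the underlying
#' behaviour taxonomy is qualitative, so the operational criteria are stated
#' in every output):
#' \enumerate{
#'   \item \strong{integrated}: the median ICE-attB distance over the final
#'     half of the distance series is below `integration_d` and no
#'     distance step there exceeds `integration_step` (the element sits on
#'     its target, at the ~200 nm offset expected from the label geometry);
#'   \item else \strong{mobile_fast}: some frame-to-frame displacement
#'     exceeds `step` and the longitudinal span exceeds `span_frac` of the
#'     cell length (fast, cell-spanning search);
#'   \item else \strong{mobile_local}: some displacement exceeds `step`;
#'   \item else \strong{trapped}.
#' }
#'
#' @param ice ICE trajectory data.frame (`frame`, `x_nm`, `y_nm`).
#' @param dist distance series from [nearest_attb_distance()] (`frame`,
#'   `d_nm`), or `NULL` (labels then restricted to the mobility classes and
#'   flagged).
#' @param cell_length cell length, nm.
#' @param thresholds named list: `integration_d` (nm, default 300),
#'   `integration_step` (nm, 500), `step` (nm, 200), `span_frac` (0.4).
#' @return list with `label`, `evidence` (one-row data.frame: median
#'   nearest-attB distance in the final half, max distance step there, max
#'   2D displacement, longitudinal span fraction, radius of gyration) and
#'   `flag`.
#' @export
classify_ice <- function(ice, dist, cell_length,
                         thresholds = list(integration_d = 300,
                                           integration_step = 500,
                                           step = 200, span_frac = 0.4)) {
  stopifnot(nrow(ice) >= 2, cell_length > 0)
  ice <- ice[order(ice$frame), ]
  consec <- diff(ice$frame) == 1L
  steps <- sqrt(diff(ice$x_nm)^2 + diff(ice$y_nm)^2)[consec]
  max_step <- if (length(steps)) max(steps) else 0
  span_frac <- (max(ice$y_nm) - min(ice$y_nm)) / cell_length
  rg <- sqrt(mean((ice$x_nm - mean(ice$x_nm))^2 +
                    (ice$y_nm - mean(ice$y_nm))^2))
  median_d <- NA_real_
  max_dstep <- NA_real_
  flag <- NA_character_
  label <- NULL
  if (!is.null(dist) && nrow(dist) >= 2) {
    dist <- dist[order(dist$frame), ]
    half <- dist[dist$frame >= stats::median(dist$frame), , drop = FALSE]
    median_d <- stats::median(half$d_nm)
    dsteps <- abs(diff(half$d_nm))[diff(half$frame) == 1L]
    max_dstep <- if (length(dsteps)) max(dsteps) else 0
    if (median_d < thresholds$integration_d &&
        max_dstep <= thresholds$integration_step) {
      label <- "integrated"
    }
  } else {
    flag <- "no distance series: integration not assessable"
  }
  if (is.null(label)) {
    label <- if (max_step > thresholds$step &&
                 span_frac > thresholds$span_frac) {
      "mobile_fast"
    } else if (max_step > thresholds$step) {
      "mobile_local"
    } else {
      "trapped"
    }
  }
  list(
    label = label,
    evidence = data.frame(median_d_nm = median_d, max_dstep_nm = max_dstep,
                          max_step_nm = max_step, span_frac = span_frac,
                          rg_nm = rg),
    flag = flag
  )
}

#' Classify every ICE trajectory of a population
#'
#' Applies [classify_ice()] per cell, using the nearest-attB distance series
#' computed from the red-channel trajectories of the same cell.
#'
#' @param tracks long trajectory table (`cell_id`, `locus_id`, `channel`,
#'   `frame`, `time_s`, `x_nm`, `y_nm`).
#' @param cell_lengths data.frame with `cell_id`, `length_nm`.
#' @param thresholds see [classify_ice()].
#' @return object of class `behavior_labels`: `$labels` (one row per cell:
#'   label plus evidence) and `$fractions` (per-class counts, fractions, and
#'   binomial standard errors).
#' @export
classify_population <- function(tracks, cell_lengths,
                                thresholds = list(integration_d = 300,
                                                  integration_step = 500,
                                                  step = 200,
                                                  span_frac = 0.4)) {
  rows <- lapply(split(tracks, tracks$cell_id), function(ct) {
    ice <- ct[ct$channel == "green", ]
    attbs <- split_tracks(ct[ct$channel == "red", ])
    if (nrow(ice) < 2 || length(attbs) == 0) return(NULL)
    d <- tryCatch(nearest_attb_distance(ice, attbs),
                  error = function(e) NULL)
    L <- cell_lengths$length_nm[match(ct$cell_id[1], cell_lengths$cell_id)]
    cl <- classify_ice(ice, d, L, thresholds)
    cbind(data.frame(cell_id = ct$cell_id[1], label = cl$label),
          cl$evidence)
  })
  labels <- do.call(rbind, rows)
  structure(
    list(labels = labels, fractions = class_fractions(labels$label),
         thresholds = thresholds),
    class = "behavior_labels"
  )
}

#' Class fractions with binomial standard errors
#'
#' @param labels character vector of behaviour labels.
#' @return data.frame with `label`, `n`, `fraction`, `se` (binomial
#'   approximation), including the pooled mobile classes.
#' @export
class_fractions <- function(labels) {
  n <- length(labels)
  lv <- c("integrated", "mobile_fast", "mobile_local", "trapped")
  cnt <- table(factor(labels, levels = lv))
  cnt <- c(cnt, mobile_any = sum(cnt[c("mobile_fast", "mobile_local")]))
  p <- as.numeric(cnt) / n
  data.frame(label = names(cnt), n = as.integer(cnt), fraction = p,
             se = sqrt(p * (1 - p) / n), row.names = NULL)
}

#' @export
print.behavior_labels <- function(x, ...) {
  cat(sprintf("Behaviour classification of %d cells\n", nrow(x$labels)))
  cat(sprintf("  thresholds: integration %g nm (step <= %g nm), mobility %g nm, span > %g L\n",
              x$thresholds$integration_d, x$thresholds$integration_step,
              x$thresholds$step, x$thresholds$span_frac))
  df <- x$fractions
  df$pct <- sprintf("%.1f +/- %.1f %%", 100 * df$fraction, 100 * df$se)
  print(df[, c("label", "n", "pct")], row.names = FALSE)
  invisible(x)
}

#' Keep only trajectories showing large displacements
#'
#' Retains trajectories with at least one frame-to-frame displacement larger
#' than `step_nm` (the rule used to exclude integrated, essentially immobile
#' elements before pooling positions).
#'
#' @param trajs list of trajectory data.frames.
#' @param step_nm displacement threshold, nm (default 200).
#' @return the filtered list.
#' @export
mobility_filter <- function(trajs, step_nm = 200) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  keep <- vapply(trajs, function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) return(FALSE)
    consec <- diff(tr$frame) == 1L
    st <- sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)[consec]
    any(st > step_nm)
  }, logical(1))
  trajs[keep]
}

#' Normalized longitudinal position distribution
#'
#' Pools the longitudinal positions of all frames of the supplied
#' trajectories, normalizes each by its cell length
#' (`fraction = (y + L/2) / L`, 0 and 1 being the poles) and histograms the
#' fractions. Because pole identity is arbitrary, the histogram can also be
#' pole-folded (`fold = TRUE`: counts averaged with their mirror image).
#'
#' @param trajs list of trajectory data.frames (with `cell_id`).
#' @param cell_lengths data.frame with `cell_id`, `length_nm`.
#' @param nbins number of uniform bins on `[0, 1]`.
#' @param fold pole-fold the histogram.
#' @param tol_frac positions outside `[-tol, 1 + tol]` are dropped (and
#'   counted in `$n_dropped`).
#' @return object of class `position_distribution`: bin mids, counts,
#'   density, `n`, `n_dropped`, `peaks` (bin mids of local maxima, highest
#'   first), and the fold flag.
#' @export
position_distribution <- function(trajs, cell_lengths, nbins = 25L,
                                  fold = FALSE, tol_frac = 0.05) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  fracs <- unlist(lapply(trajs, function(tr) {
    L <- cell_lengths$length_nm[match(tr$cell_id[1], cell_lengths$cell_id)]
    (tr$y_nm + L / 2) / L
  }), use.names = FALSE)
  ok <- fracs >= -tol_frac & fracs <= 1 + tol_frac
  n_dropped <- sum(!ok)
  fr <- pmin(pmax(fracs[ok], 0), 1 - 1e-12)
  breaks <- seq(0, 1, length.out = nbins + 1)
  counts <- tabulate(findInterval(fr, breaks, rightmost.closed = TRUE),
                     nbins)
  if (fold) counts <- (counts + rev(counts)) / 2
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  dens <- counts / sum(counts) / (1 / nbins)
  inner <- 2:(nbins - 1)
  is_peak <- rep(FALSE, nbins)
  is_peak[inner] <- counts[inner] >= counts[inner - 1] &
    counts[inner] >= counts[inner + 1] &
    counts[inner] > stats::median(counts)
  peaks <- mids[is_peak][order(counts[is_peak], decreasing = TRUE)]
  structure(
    list(mids = mids, counts = counts, density = dens,
         n = sum(counts), n_dropped = n_dropped, peaks = peaks,
         folded = fold, nbins = nbins),
    class = "position_distribution"
  )
}

#' @export
print.position_distribution <- function(x, ...) {
  cat(sprintf(
    "Longitudinal position distribution: n = %d positions, %d bins%s\n",
    round(x$n), x$nbins, if (x$folded) " (pole-folded)" else ""))
  if (length(x$peaks)) {
    cat("  peaks at:", paste(signif(head(x$peaks, 4), 3), collapse = ", "),
        "\n")
  }
  if (x$n_dropped > 0) cat("  dropped outside cell:", x$n_dropped, "\n")
  invisible(x)
}

#' @export
plot.position_distribution <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h", lwd = 4, lend = 1,
                 xlab = "normalized longitudinal position",
                 ylab = "density", ...)
  invisible(x)
}
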