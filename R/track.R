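#' Link per-frame detections into trajectories
#'
#' Links detections frame by frame, per cell and per channel. The default is
#' greedy nearest-neighbour assignment (cost = Euclidean distance in the cell
#' frame, matches above `max_disp` rejected) with gap closing up to `max_gap`
#' missed frames; since at most two spots per channel are kept per cell, a
#' globally optimal assignment is also available by exhaustive enumeration
#' (`method = "optimal"`) for validation. Ties are broken by smaller
#' distance, then lower track id, then detection order, so linking is
#' deterministic and permutation-invariant to the input row order.
#'
#' @param detections data.frame with `cell_id`, `channel`, `frame`, `time_s`,
#'   `x_nm`, `y_nm` (cell-frame coordinates).
#' @param max_disp maximum frame-to-frame displacement, nm (default 800,
#'   sized for ~4 s framing of the fastest elements).
#' @param max_gap maximum number of consecutive missed frames bridged.
#' @param min_len minimum trajectory length kept, frames.
#' @param method `"greedy"` or `"optimal"` (exhaustive, n <= 6 per frame).
#' @return long trajectory table: `cell_id`, `locus_id`, `channel`, `frame`,
#'   `time_s`, `x_nm`, `y_nm`.
#' @export
link_trajectories <- function(detections, max_disp = 800, max_gap = 2L,
                              min_len = 20L, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  need <- c("cell_id", "channel", "frame", "time_s", "x_nm", "y_nm")
  stopifnot(all(need %in% names(detections)))
  det <- detections[order(detections$cell_id, detections$channel,
                          detections$frame, detections$x_nm,
                          detections$y_nm), ]
  out <- lapply(split(det, list(det$cell_id, det$channel), drop = TRUE),
                function(d) .link_one(d, max_disp, max_gap, method))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res) || nrow(res) == 0) return(res)
  keylen <- stats::ave(res$frame,
                       interaction(res$cell_id, res$channel, res$locus_id,
                                   drop = TRUE),
                       FUN = length)
  res <- res[keylen >= min_len, ]
  rownames(res) <- NULL
  res
}

# Assign detections of one cell/channel stream to tracks.
.link_one <- function(d, max_disp, max_gap, method) {
  frames <- sort(unique(d$frame))
  tracks <- list() # each: list(rows = df, last_xy, last_frame, open)
  for (f in frames) {
    df <- d[d$frame == f, , drop = FALSE]
    open <- which(vapply(tracks, function(tr) {
      tr$open && (f - tr$last_frame) <= (max_gap + 1L)
    }, logical(1)))
    nd <- nrow(df)
    assign_det <- rep(NA_integer_, nd)
    if (length(open) && nd) {
      cost <- outer(open, seq_len(nd), Vectorize(function(ti, di) {
        sqrt((tracks[[ti]]$last_xy[1] - df$x_nm[di])^2 +
               (tracks[[ti]]$last_xy[2] - df$y_nm[di])^2)
      }))
      cost[cost > max_disp] <- Inf
      if (method == "optimal" && length(open) <= 6L && nd <= 6L) {
        assign_det <- .assign_optimal(cost, open)
      } else {
        assign_det <- .assign_greedy(cost, open)
      }
    }
    for (di in seq_len(nd)) {
      ti <- assign_det[di]
      row <- df[di, , drop = FALSE]
      if (!is.na(ti)) {
        tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows, row)
        tracks[[ti]]$last_xy <- c(row$x_nm, row$y_nm)
        tracks[[ti]]$last_frame <- f
      } else {
        tracks[[length(tracks) + 1L]] <- list(
          rows = row, last_xy = c(row$x_nm, row$y_nm), last_frame = f,
          open = TRUE)
      }
    }
    for (ti in seq_along(tracks)) {
      if (tracks[[ti]]$open && (f - tracks[[ti]]$last_frame) > max_gap) {
        tracks[[ti]]$open <- FALSE
      }
    }
  }
  do.call(rbind, lapply(seq_along(tracks), function(ti) {
    r <- tracks[[ti]]$rows
    r$locus_id <- ti
    r[, c("cell_id", "locus_id", "channel", "frame", "time_s",
          "x_nm", "y_nm")]
  }))
}

# Greedy: repeatedly take the globally smallest finite cost; deterministic
# tie-break on row (track) then column (detection) order.
.assign_greedy <- function(cost, open) {
  nd <- ncol(cost)
  assign_det <- rep(NA_integer_, nd)
  cost <- matrix(cost, nrow = length(open))
  while (any(is.finite(cost))) {
    ij <- which(cost == min(cost), arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE][1L, ]
    assign_det[ij[2L]] <- open[ij[1L]]
    cost[ij[1L], ] <- Inf
    cost[, ij[2L]] <- Inf
  }
  assign_det
}

# Exhaustive optimal assignment over all injections of detections to tracks.
.assign_optimal <- function(cost, open) {
  nt <- length(open)
  nd <- ncol(cost)
  best <- NULL
  best_cost <- Inf
  # enumerate detection -> track maps (0 = unmatched)
  grid <- expand.grid(rep(list(0:nt), nd))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    cc <- 0
    ok <- TRUE
    for (di in seq_len(nd)) {
      if (a[di] > 0) {
        v <- cost[a[di], di]
        if (!is.finite(v)) { ok <- FALSE; break }
        cc <- cc + v
      } else {
        cc <- cc + 1e7 # penalty for leaving a detection unmatched
      }
    }
    if (ok && cc < best_cost - 1e-12) {
      best_cost <- cc
      best <- a
    }
  }
  if (is.null(best)) return(rep(NA_integer_, nd))
  ifelse(best > 0, open[best], NA_integer_)
}

#' Distance from an ICE to its nearest attB locus over time
#'
#' Per frame in which the ICE and at least one attB locus were both
#' detected, the minimum Euclidean distance (cell-frame nm) from the ICE to
#' any attB locus.
#'
#' @param ice ICE trajectory data.frame.
#' @param attbs list of attB trajectory data.frames (same cell).
#' @return data.frame `frame`, `time_s`, `d_nm`.
#' @export
nearest_attb_distance <- function(ice, attbs) {
  if (is.data.frame(attbs)) attbs <- list(attbs)
  stopifnot(nrow(ice) >= 1, length(attbs) >= 1)
  d_all <- lapply(attbs, function(ab) {
    i <- match(ice$frame, ab$frame)
    sqrt((ice$x_nm - ab$x_nm[i])^2 + (ice$y_nm - ab$y_nm[i])^2)
  })
  d <- do.call(pmin, c(d_all, list(na.rm = TRUE)))
  keep <- is.finite(d)
  if (!any(keep)) stop("no common frames between ICE and attB trajectories")
  data.frame(frame = ice$frame[keep], time_s = ice$time_s[keep],
             d_nm = d[keep])
}
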