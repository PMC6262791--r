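#' Tracked-cell trajectory
#'
#' Ordered 4D samples of one tracked nucleus: timestamps in minutes and 3D
#' positions in micrometres. Timestamps must be strictly increasing and
#' uniformly spaced (within 1% of the median interval); tracks with gaps
#' are rejected rather than interpolated, since manual tracking is gap-free
#' by construction.
#'
#' @param track_id identifier.
#' @param t timestamps, minutes.
#' @param x,y,z positions, micrometres.
#' @return a `trajectory` (data frame `t`, `x`, `y`, `z` with attributes
#'   `track_id` and `dt`).
#' @export
trajectory <- function(track_id, t, x, y, z) {
  if (length(t) < 2L) stop("a trajectory needs at least 2 samples")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 0.01 * dt))
    stop(sprintf("track %s has non-uniform sampling (gap?); tracks with gaps are rejected",
                 track_id))
  structure(data.frame(t = t, x = x, y = y, z = z),
            class = c("trajectory", "data.frame"),
            track_id = track_id, dt = dt)
}

#' Trajectory kinematics: speed, path length, net displacement
#'
#' The three per-cell motility metrics: total 3D path length (sum of
#' inter-sample step lengths), 3D net displacement (straight-line distance
#' from first to last position), and average speed defined as path length
#' over elapsed time (identical to the mean of framewise speeds under
#' uniform sampling).
#'
#' @param traj a [trajectory()].
#' @return list with `avg_speed` (um/min), `path_length` (um),
#'   `net_displacement` (um).
#' @examples
#' tr <- trajectory("a", t = c(0, 2.75, 5.5), x = c(0, 1, 2), y = 0, z = 0)
#' track_metrics(tr)
#' @export
track_metrics <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory")
  p <- as.matrix(traj[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(p)^2))
  path <- sum(steps)
  net <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  elapsed <- traj$t[nrow(traj)] - traj$t[1]
  list(avg_speed = path / elapsed, path_length = path, net_displacement = net)
}

#' Tracking QC: nuclear pixel overlap between consecutive time points
#'
#' Accepts a track step when the nuclear masks at consecutive time points
#' share at least `threshold` of their pixels. The overlap fraction is
#' normalized by the smaller mask (the permissive convention for a manual
#' tracking acceptance check); the default threshold is the 50% used in
#' the tracking workflow.
#'
#' @param mask_t,mask_t1 logical arrays (2D or 3D) of identical shape,
#'   each nonempty.
#' @param threshold minimum acceptable overlap fraction.
#' @return list with `ok` (logical) and `fraction`
#'   (`|A and B| / min(|A|, |B|)`).
#' @export
overlap_ok <- function(mask_t, mask_t1, threshold = 0.5) {
  if (!identical(dim(mask_t), dim(mask_t1)))
    stop("masks must have identical shape")
  na <- sum(mask_t); nb <- sum(mask_t1)
  if (na == 0L || nb == 0L) stop("empty nuclear mask")
  frac <- sum(mask_t & mask_t1) / min(na, nb)
  list(ok = frac >= threshold, fraction = frac)
}

#' Per-group summary of track metrics
#'
#' Mean and sample (n-1) standard deviation per metric per group, the
#' reporting convention used for grouped motility measurements. Groups with
#' a single track report s.d. 0 and are flagged.
#'
#' @param metrics data frame with columns `avg_speed`, `path_length`,
#'   `net_displacement` (one row per track), e.g. from
#'   [track_metrics_table()].
#' @param groups group label per track (same length as rows of `metrics`).
#' @return data frame, one row per group x metric: `group`, `metric`, `n`,
#'   `mean`, `sd`, `single_track` flag.
#' @export
group_summary <- function(metrics, groups) {
  if (nrow(metrics) == 0L) stop("no tracks")
  if (length(groups) != nrow(metrics))
    stop("`groups` must have one label per track")
  if (any(is.na(groups))) stop("empty (NA) group label")
  cols <- c("avg_speed", "path_length", "net_displacement")
  out <- do.call(rbind, lapply(sort(unique(as.character(groups))), function(gr) {
    sel <- metrics[groups == gr, cols, drop = FALSE]
    do.call(rbind, lapply(cols, function(cl) {
      v <- sel[[cl]]
      data.frame(group = gr, metric = cl, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 single_track = length(v) == 1L)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read tracked centroid tables and compute per-track metrics
#'
#' @param path CSV with columns `track_id,t_min,x_um,y_um,z_um`.
#' @return list of [trajectory()] objects, one per track.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t_min", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop(sprintf("track CSV must have columns %s", paste(need, collapse = ", ")))
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$t_min), ]
    trajectory(d$track_id[1], d$t_min, d$x_um, d$y_um, d$z_um)
  })
}

#' Metrics table for a set of trajectories
#' @param trajs list of [trajectory()] objects.
#' @return data frame with one row per track (`track_id`, `avg_speed`,
#'   `path_length`, `net_displacement`).
#' @export
track_metrics_table <- function(trajs) {
  out <- do.call(rbind, lapply(trajs, function(tr) {
    m <- track_metrics(tr)
    data.frame(track_id = attr(tr, "track_id"), avg_speed = m$avg_speed,
               path_length = m$path_length, net_displacement = m$net_displacement,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a trajectory (or list of trajectories) to CSV
#' @param trajs a [trajectory()] or list of them.
#' @param path output CSV (`track_id,t_min,x_um,y_um,z_um`).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(track_id = attr(tr, "track_id"), t_min = tr$t,
               x_um = tr$x, y_um = tr$y, z_um = tr$z)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
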