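#' Clip a kinematic stream to a set of time windows
#'
#' Keeps the samples lying inside the half-open windows and tags each with
#' the index of its covering window (`window_id`). Samples in different
#' windows are discontinuous: no distance may be accumulated across a window
#' boundary, and [path_length()] honors that. No interpolation is performed
#' at window edges.
#'
#' @param traj data.frame with `time_s`, `x_cm`, `y_cm`, `z_cm` (e.g. from
#'   [get_stream()]).
#' @param windows normalized interval matrix ([iv_normalize()]) or a
#'   two-column matrix/data.frame of disjoint ordered `[start, end)` windows.
#' @return the clipped data.frame with a `window_id` column (possibly 0 rows).
#' @export
clip_stream <- function(traj, windows) {
  windows <- as_windows(windows)
  id <- iv_locate(traj$time_s, windows)
  out <- traj[!is.na(id), , drop = FALSE]
  out$window_id <- id[!is.na(id)]
  rownames(out) <- NULL
  out
}

as_windows <- function(w) {
  if (is.data.frame(w)) w <- cbind(start = w$start_s %||% w$start,
                                   end = w$end_s %||% w$end)
  if (is.null(dim(w))) w <- matrix(w, ncol = 2,
                                   dimnames = list(NULL, c("start", "end")))
  iv_normalize(w[, 1], w[, 2])
}

#' Instrument path length
#'
#' Total distance traveled: the sum of Euclidean distances between
#' consecutive samples of a clipped stream, never accumulating across a
#' window discontinuity. Fewer than two samples give 0.
#'
#' @param traj a clipped stream from [clip_stream()] (a plain stream without
#'   `window_id` is treated as one continuous window).
#' @return path length in cm.
#' @examples
#' tr <- data.frame(time_s = 0:1, x_cm = c(0, 3), y_cm = c(0, 4), z_cm = 0)
#' path_length(tr)  # 5
#' @export
path_length <- function(traj) {
  n <- nrow(traj)
  if (is.null(n) || n < 2L) return(0)
  d <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2 + diff(traj$z_cm)^2)
  if (!is.null(traj$window_id))
    d[diff(traj$window_id) != 0] <- 0
  sum(d)
}

#' Active time within step windows
#'
#' Total duration of the intersection between a set of activity intervals
#' (console- or hand-scope) and the step windows. Both operands are
#' half-open, so the result is exact.
#'
#' @param intervals normalized activity interval matrix.
#' @param windows step windows (any form accepted by [clip_stream()]).
#' @return seconds.
#' @export
active_time <- function(intervals, windows) {
  iv_length(iv_intersect(as_windows(intervals), as_windows(windows)))
}

#' Elementary OPI ratios
#'
#' Small, explicitly-guarded ratio metrics. Undefined values (zero
#' denominators) propagate as `NA`, never as 0 or `Inf`, so that downstream
#' statistics drop them per case rather than biasing a group.
#'
#' * `pct_active()`: percentage of the task duration a console/hand was
#'   active, `100 * active_s / total_s`, in `[0, 100]`.
#' * `instrument_speed()`: mean tip speed during active console time,
#'   `pathlength_cm / active_s` (cm/s).
#' * `bimanual_dexterity()`: dominant over non-dominant instrument path
#'   length; values above 1 mean greater dominant-hand travel.
#' * `console_sensitivity()`: instrument-tip over console-wrist path length —
#'   the master-slave motion scaling, a per-case diagnostic.
#'
#' @param active_s,total_s,pathlength_cm,pl_dom_cm,pl_nondom_cm,instrument_pl_cm,wrist_pl_cm
#'   numeric scalars (vectorized).
#' @return numeric.
#' @name opi_ratios
NULL

#' @rdname opi_ratios
#' @export
pct_active <- function(active_s, total_s) {
  out <- ifelse(total_s > 0, 100 * active_s / total_s, NA_real_)
  if (any(total_s <= 0, na.rm = TRUE))
    warn_opikin("pct_active undefined for zero task duration")
  pmin(pmax(out, 0), 100)
}

#' @rdname opi_ratios
#' @export
instrument_speed <- function(pathlength_cm, active_s) {
  bad <- active_s <= 0 & pathlength_cm > 0
  if (any(bad, na.rm = TRUE))
    warn_opikin("positive path length with zero active time; speed undefined")
  ifelse(active_s > 0, pathlength_cm / active_s,
         ifelse(pathlength_cm == 0, NA_real_, NA_real_))
}

#' @rdname opi_ratios
#' @export
bimanual_dexterity <- function(pl_dom_cm, pl_nondom_cm) {
  ifelse(pl_nondom_cm > 0, pl_dom_cm / pl_nondom_cm, NA_real_)
}

#' @rdname opi_ratios
#' @export
console_sensitivity <- function(instrument_pl_cm, wrist_pl_cm) {
  ifelse(wrist_pl_cm > 0, instrument_pl_cm / wrist_pl_cm, NA_real_)
}

#' Workspace volume of instrument-tip motion
#'
#' The total volume of space occupied by instrument movement, measured as
#' the volume of the convex hull of the pooled 3D tip positions (both hands,
#' restricted to active windows). Fewer than four points, or a degenerate
#' (collinear/coplanar) cloud, give 0 with a degeneracy message.
#'
#' @param points numeric matrix (n x 3) or data.frame with `x_cm`, `y_cm`,
#'   `z_cm`.
#' @return hull volume in cm^3.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' workspace_volume(cube)  # 1
#' @export
workspace_volume <- function(points) {
  if (is.data.frame(points))
    points <- as.matrix(points[, c("x_cm", "y_cm", "z_cm")])
  storage.mode(points) <- "double"
  if (nrow(points) < 4L) {
    message("workspace_volume: fewer than 4 points; degenerate hull, volume 0")
    return(0)
  }
  v <- .hull3d_volume(points)
  if (v == 0)
    message("workspace_volume: degenerate (collinear/coplanar) cloud, volume 0")
  v
}

#' Normalize workspace volume
#'
#' Workspace volume grows with how long and how far the instruments move, so
#' raw volumes are not comparable across steps or cases. Two normalizations
#' remove that dependence: per second of active console time (cm^3/s) and per
#' centimeter of total instrument path length (cm^2). Both are reported; a
#' consistent significance finding under both indicates the workspace effect
#' is not an artifact of the chosen denominator.
#'
#' @param volume_cm3 hull volume.
#' @param active_s active console time (s).
#' @param total_pathlength_cm summed both-hand instrument path length.
#' @return named list `rate_cm3_s`, `per_pathlength_cm2` (`NA` where the
#'   denominator is 0).
#' @export
normalize_workspace <- function(volume_cm3, active_s, total_pathlength_cm) {
  list(rate_cm3_s = ifelse(active_s > 0, volume_cm3 / active_s, NA_real_),
       per_pathlength_cm2 = ifelse(total_pathlength_cm > 0,
                                   volume_cm3 / total_pathlength_cm,
                                   NA_real_))
}
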