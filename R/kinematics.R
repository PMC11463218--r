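#' Euclidean distance between 3D points
#'
#' `sqrt((x2-x1)^2 + (y2-y1)^2 + (z2-z1)^2)`, vectorized over rows.
#'
#' @param p,q data frames with `x_cm`, `y_cm`, `z_cm` (or length-3 numeric
#'   vectors).
#' @return Numeric vector of distances in cm.
#' @export
euclidean_distance <- function(p, q) {
  if (!is.data.frame(p)) p <- data.frame(x_cm = p[1], y_cm = p[2], z_cm = p[3])
  if (!is.data.frame(q)) q <- data.frame(x_cm = q[1], y_cm = q[2], z_cm = q[3])
  sqrt((q$x_cm - p$x_cm)^2 + (q$y_cm - p$y_cm)^2 + (q$z_cm - p$z_cm)^2)
}

#' Per-step path lengths of a trajectory
#'
#' Distance between each pair of consecutive trajectory points. A step whose
#' endpoints are separated by more than one frame spans an unfilled gap; it
#' is reported but marked excluded, so path length is never fabricated across
#' occlusions.
#'
#' @param traj a [trajectory()] with at least 2 points.
#' @return Data frame `from_frame`, `to_frame`, `length_cm`, `included`.
#' @export
step_series <- function(traj) {
  pts <- traj$points
  if (nrow(pts) < 2) stop("step_series needs at least 2 points")
  i <- seq_len(nrow(pts) - 1L)
  data.frame(from_frame = pts$frame_index[i],
             to_frame = pts$frame_index[i + 1L],
             length_cm = euclidean_distance(pts[i, ], pts[i + 1L, ]),
             included = diff(pts$frame_index) == 1L)
}

#' Velocity and cumulative-distance profile of a trajectory
#'
#' Instantaneous velocity at sample i is the backward difference: the step
#' from sample i-1 divided by the sampling interval; the first sample's
#' velocity is 0. Cumulative distance is the running sum of included steps.
#' Steps across unfilled gaps are excluded (velocity `NA`, no distance
#' added) unless `bridge_gaps` straight-lines them for comparison.
#'
#' @param traj a [trajectory()].
#' @param bridge_gaps also count steps spanning unfilled gaps (as straight
#'   chords over the elapsed time).
#' @return Data frame `timestamp_s`, `velocity_cm_s`, `cumulative_cm`.
#' @export
kinematic_profile <- function(traj, bridge_gaps = FALSE) {
  pts <- traj$points
  if (nrow(pts) < 2) stop("kinematic_profile needs at least 2 points")
  steps <- step_series(traj)
  use <- steps$included | bridge_gaps
  dt_step <- diff(pts$timestamp_s)
  vel <- c(0, ifelse(use, steps$length_cm / dt_step, NA_real_))
  cum <- c(0, cumsum(ifelse(use, steps$length_cm, 0)))
  data.frame(timestamp_s = pts$timestamp_s,
             velocity_cm_s = vel,
             cumulative_cm = cum)
}

#' @rdname kinematic_profile
#' @param path output CSV (`timestamp_s,velocity_cm_s,cumulative_cm`).
#' @export
write_kinematics_csv <- function(traj, path, bridge_gaps = FALSE) {
  utils::write.csv(kinematic_profile(traj, bridge_gaps), path,
                   row.names = FALSE)
  invisible(path)
}
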