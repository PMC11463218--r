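#' Merge a top-view and a side-view planar point into a 3D coordinate
#'
#' The two orthogonal views share the tank's X axis: the top view supplies
#' (X, Y), the side view (X, Z). X is taken as the mean of the two views'
#' estimates and their absolute difference is recorded as
#' `x_disagreement_cm`; a disagreement above `x_tolerance_cm` flags the point
#' as a suspect pairing but still produces it.
#'
#' @param top_pt,side_pt planar points (data frames with `a_cm`, `b_cm`,
#'   `timestamp_s`); may have several rows, matched positionally.
#' @param x_tolerance_cm disagreement above which a point is flagged.
#' @return Data frame with `timestamp_s`, `x_cm`, `y_cm`, `z_cm`,
#'   `x_disagreement_cm`, `suspect`, `provenance = "observed"`.
#' @export
merge_views <- function(top_pt, side_pt, x_tolerance_cm = 1) {
  if (nrow(top_pt) != nrow(side_pt)) {
    stop("top and side planar point sets differ in length")
  }
  if (any(abs(top_pt$timestamp_s - side_pt$timestamp_s) > 1e-9)) {
    stop("mismatched timestamps between views")
  }
  disagreement <- abs(top_pt$a_cm - side_pt$a_cm)
  data.frame(timestamp_s = top_pt$timestamp_s,
             x_cm = (top_pt$a_cm + side_pt$a_cm) / 2,
             y_cm = top_pt$b_cm,
             z_cm = side_pt$b_cm,
             x_disagreement_cm = disagreement,
             suspect = disagreement > x_tolerance_cm,
             provenance = "observed",
             stringsAsFactors = FALSE)
}

# px_to_tank that marks beyond-slack points instead of erroring
px_to_tank_safe <- function(p, cam, tank, slack_px) {
  r <- cam$roi
  out_u <- pmax(r[1] - p$u, p$u - r[3], 0)
  out_v <- pmax(r[2] - p$v, p$v - r[4], 0)
  ok <- out_u <= slack_px & out_v <= slack_px
  coords <- data.frame(a_cm = rep(NA_real_, nrow(p)), b_cm = NA_real_)
  if (any(ok)) coords[ok, ] <- px_to_tank(p[ok, , drop = FALSE], cam, tank,
                                          slack_px)[, c("a_cm", "b_cm")]
  coords$ok <- ok
  coords
}

# one planar point per frame for one view: confidence filter, then the most
# confident detection, then center -> tank plane
primary_planar <- function(stream, cam, tank, conf_threshold, dt, slack_px) {
  kept <- filter_by_confidence(stream, conf_threshold)
  if (nrow(kept) == 0) {
    return(list(points = data.frame(frame_index = integer(),
                                    timestamp_s = numeric(),
                                    a_cm = numeric(), b_cm = numeric()),
                skipped = integer()))
  }
  ord <- order(kept$frame_index, -kept$confidence)
  kept <- kept[ord, , drop = FALSE]
  kept <- kept[!duplicated(kept$frame_index), , drop = FALSE]
  ctr <- bbox_center_px(kept, cam)
  coords <- px_to_tank_safe(ctr, cam, tank, slack_px)
  list(points = data.frame(frame_index = kept$frame_index,
                           timestamp_s = kept$frame_index * dt,
                           a_cm = coords$a_cm,
                           b_cm = coords$b_cm)[coords$ok, , drop = FALSE],
       skipped = kept$frame_index[!coords$ok])
}

#' Reconstruct the per-frame 3D coordinate series from paired streams
#'
#' For every synchronized frame: filter each view by confidence, keep the
#' most confident detection, map its box center into tank coordinates, and
#' merge the two views on the shared X axis. A frame missing either view's
#' detection yields a gap; a frame whose detection center falls outside the
#' ROI (beyond the pixel slack) is recorded as skipped, never aborting.
#'
#' @param pairs a [pair_streams()] object.
#' @param cameras named list with `top` and `side` [camera_config()]s.
#' @param tank a [tank_geometry()].
#' @param conf_threshold confidence cutoff applied to both views.
#' @param x_tolerance_cm passed to [merge_views()].
#' @param slack_px ROI tolerance passed to the pixel-to-tank map.
#' @return A `recon_series`: data frame over all synchronized frames with
#'   `frame_index`, `timestamp_s`, `x_cm`, `y_cm`, `z_cm`,
#'   `x_disagreement_cm`, `suspect`, `provenance` (`"observed"` or `NA` for
#'   gaps). Attributes: `skipped` (frames dropped by geometry errors, with the
#'   offending view), `single_view` (frames observed in exactly one view).
#' @export
reconstruct_sequence <- function(pairs, cameras, tank, conf_threshold = 0,
                                 x_tolerance_cm = 1, slack_px = 2) {
  stopifnot(inherits(pairs, "sync_pairs"))
  dt <- pairs$dt
  top <- primary_planar(pairs$top, cameras$top, tank, conf_threshold, dt, slack_px)
  side <- primary_planar(pairs$side, cameras$side, tank, conf_threshold, dt, slack_px)
  common <- intersect(top$points$frame_index, side$points$frame_index)
  ti <- match(common, top$points$frame_index)
  si <- match(common, side$points$frame_index)
  merged <- merge_views(top$points[ti, , drop = FALSE],
                        side$points[si, , drop = FALSE], x_tolerance_cm)
  merged$frame_index <- common

  frames <- pairs$frames$frame_index
  series <- data.frame(frame_index = frames, timestamp_s = frames * dt,
                       x_cm = NA_real_, y_cm = NA_real_, z_cm = NA_real_,
                       x_disagreement_cm = NA_real_, suspect = NA,
                       provenance = NA_character_, stringsAsFactors = FALSE)
  at <- match(merged$frame_index, frames)
  series[at, c("x_cm", "y_cm", "z_cm", "x_disagreement_cm")] <-
    merged[, c("x_cm", "y_cm", "z_cm", "x_disagreement_cm")]
  series$suspect[at] <- merged$suspect
  series$provenance[at] <- "observed"

  skipped <- rbind(
    if (length(top$skipped)) data.frame(frame_index = top$skipped, view = "top"),
    if (length(side$skipped)) data.frame(frame_index = side$skipped, view = "side"))
  only_top <- setdiff(top$points$frame_index, common)
  only_side <- setdiff(side$points$frame_index, common)
  single <- rbind(
    if (length(only_top)) data.frame(frame_index = only_top, view = "top"),
    if (length(only_side)) data.frame(frame_index = only_side, view = "side"))
  structure(series, skipped = skipped, single_view = single,
            dt_s = dt, class = c("recon_series", "data.frame"))
}

#' Fill short interior detection gaps by linear interpolation
#'
#' Interior gaps of at most `max_gap_frames` missing frames are filled
#' per-axis linearly between the flanking observed points and marked
#' `provenance = "interpolated"`. Longer gaps and leading/trailing gaps are
#' never filled (no extrapolation) and are reported.
#'
#' @param series a `recon_series` (or any data frame with `frame_index`,
#'   `timestamp_s`, coordinate columns and `provenance`).
#' @param max_gap_frames longest gap, in frames, that is filled (default 5,
#'   i.e. 0.5 s at 10 Hz).
#' @return The series with filled rows; attribute `unfilled_gaps` is a data
#'   frame `start_frame`, `end_frame`, `length` (leading/trailing gaps
#'   included).
#' @export
fill_gaps <- function(series, max_gap_frames = 5) {
  obs <- which(!is.na(series$provenance))
  if (length(obs) == 0) stop("series has no observed points")
  unfilled <- list()
  add_gap <- function(from, to) {
    unfilled[[length(unfilled) + 1]] <<-
      data.frame(start_frame = series$frame_index[from],
                 end_frame = series$frame_index[to],
                 length = to - from + 1L)
  }
  if (obs[1] > 1) add_gap(1L, obs[1] - 1L)
  if (length(obs) > 1) {
    for (k in seq_len(length(obs) - 1L)) {
      i <- obs[k]; j <- obs[k + 1L]
      g <- j - i - 1L
      if (g == 0L) next
      if (g > max_gap_frames) {
        add_gap(i + 1L, j - 1L)
        next
      }
      mid <- (i + 1L):(j - 1L)
      f <- (series$timestamp_s[mid] - series$timestamp_s[i]) /
        (series$timestamp_s[j] - series$timestamp_s[i])
      for (col in c("x_cm", "y_cm", "z_cm")) {
        series[[col]][mid] <- series[[col]][i] + f * (series[[col]][j] - series[[col]][i])
      }
      series$x_disagreement_cm[mid] <- 0
      series$suspect[mid] <- FALSE
      series$provenance[mid] <- "interpolated"
    }
  }
  n <- nrow(series)
  if (obs[length(obs)] < n) add_gap(obs[length(obs)] + 1L, n)
  gaps <- if (length(unfilled)) do.call(rbind, unfilled) else
    data.frame(start_frame = integer(), end_frame = integer(),
               length = integer())
  attr(series, "unfilled_gaps") <- gaps
  series
}

#' Construct a trajectory object
#'
#' @param points data frame with `frame_index`, `timestamp_s`, `x_cm`,
#'   `y_cm`, `z_cm`, and optionally `provenance` and `x_disagreement_cm`
#'   (defaulted to `"observed"` / 0).
#' @param dt_s nominal sampling interval in seconds.
#' @param gaps data frame of unfilled gaps (`start_frame`, `end_frame`,
#'   `length`), empty by default.
#' @return An object of class `fish_trajectory`: list with `points`, `dt_s`,
#'   `gaps`.
#' @export
trajectory <- function(points, dt_s = 0.1, gaps = NULL) {
  if (is.null(points$provenance)) points$provenance <- "observed"
  if (is.null(points$x_disagreement_cm)) points$x_disagreement_cm <- 0
  if (is.null(gaps)) {
    gaps <- data.frame(start_frame = integer(), end_frame = integer(),
                       length = integer())
  }
  if (nrow(points) > 1 && any(diff(points$timestamp_s) <= 0)) {
    stop("trajectory timestamps must be strictly increasing")
  }
  structure(list(points = points, dt_s = dt_s, gaps = gaps),
            class = "fish_trajectory")
}

#' Assemble the final trajectory from a gap-filled series
#'
#' Drops unfilled-gap frames, verifies that the remaining timestamps are
#' strictly increasing on the uniform `dt` grid, and packages the points with
#' the recorded unfilled gaps.
#'
#' @param series output of [fill_gaps()] (or a raw `recon_series`).
#' @param dt_s sampling interval; defaults to the series' own.
#' @param tol timestamp tolerance in seconds.
#' @return A [trajectory()].
#' @export
assemble_trajectory <- function(series, dt_s = NULL, tol = 1e-6) {
  if (is.null(dt_s)) dt_s <- attr(series, "dt_s")
  if (is.null(dt_s)) dt_s <- 0.1
  gaps <- attr(series, "unfilled_gaps")
  if (is.null(gaps)) {
    gaps <- data.frame(start_frame = integer(), end_frame = integer(),
                       length = integer())
  }
  pts <- series[!is.na(series$provenance), , drop = FALSE]
  if (nrow(pts) == 0) stop("no points to assemble")
  off <- abs(pts$timestamp_s - pts$frame_index * dt_s)
  if (any(off > tol)) {
    stop("timestamps deviate from the uniform dt grid beyond tolerance")
  }
  rownames(pts) <- NULL
  trajectory(pts[, c("frame_index", "timestamp_s", "x_cm", "y_cm", "z_cm",
                     "provenance", "x_disagreement_cm")],
             dt_s = dt_s, gaps = gaps)
}

#' @export
print.fish_trajectory <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("3D trajectory: %d points at dt = %g s (%.1f s span)\n",
              n, x$dt_s,
              if (n) diff(range(x$points$timestamp_s)) else 0))
  cat(sprintf("  observed %d, interpolated %d, unfilled gaps %d (%d frames)\n",
              sum(x$points$provenance == "observed"),
              sum(x$points$provenance == "interpolated"),
              nrow(x$gaps), sum(x$gaps$length)))
  invisible(x)
}

#' Write / read a trajectory CSV (with gap sidecar)
#'
#' Columns: `frame_index,timestamp_s,x_cm,y_cm,z_cm,provenance,`
#' `x_disagreement_cm`. The unfilled-gap report goes to a sidecar CSV
#' (`start_frame,end_frame,length`) next to the main file.
#'
#' @param traj a [trajectory()].
#' @param path output CSV path.
#' @param gap_path sidecar path; default replaces `.csv` with `_gaps.csv`.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path, gap_path = NULL) {
  utils::write.csv(traj$points, path, row.names = FALSE)
  if (is.null(gap_path)) gap_path <- sub("\\.csv$", "_gaps.csv", path)
  utils::write.csv(traj$gaps, gap_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param dt_s sampling interval of the stored trajectory.
#' @export
read_trajectory_csv <- function(path, gap_path = NULL, dt_s = 0.1) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(gap_path)) gap_path <- sub("\\.csv$", "_gaps.csv", path)
  gaps <- if (file.exists(gap_path)) {
    utils::read.csv(gap_path, stringsAsFactors = FALSE)
  } else NULL
  trajectory(pts, dt_s = dt_s, gaps = gaps)
}
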