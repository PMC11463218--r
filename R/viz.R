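#' Rendering style for dynamic trajectory frames
#'
#' Recency windows and colors: points from the most recent
#' `recent_window_s` seconds are drawn in deep blue, points between
#' `recent_window_s` and `mid_window_s` ago in light blue, and everything
#' older in gray.
#'
#' @param recent_window_s,mid_window_s window lengths in seconds
#'   (`0 < recent < mid`).
#' @param recent_color,mid_color,old_color hex colors.
#' @param show_overlays draw the cumulative-distance / velocity text box.
#' @return An object of class `render_style`.
#' @export
render_style <- function(recent_window_s = 1, mid_window_s = 3,
                         recent_color = "#00308F", mid_color = "#89CFF0",
                         old_color = "#BEBEBE", show_overlays = TRUE) {
  if (!(recent_window_s > 0 && recent_window_s < mid_window_s)) {
    stop("need 0 < recent_window_s < mid_window_s")
  }
  structure(list(recent_window_s = recent_window_s,
                 mid_window_s = mid_window_s,
                 recent_color = recent_color, mid_color = mid_color,
                 old_color = old_color, show_overlays = show_overlays),
            class = "render_style")
}

#' Partition past trajectory points by recency
#'
#' Exact partition of the points with `timestamp <= t_now`: *recent* points
#' lie within `recent_window_s` of `t_now`, *mid* within
#' `(recent_window_s, mid_window_s]`, *old* is the rest. Future points are
#' excluded.
#'
#' @param traj a [trajectory()].
#' @param t_now current time in seconds; must not precede the first point.
#' @param style a [render_style()].
#' @return List of integer index vectors `recent`, `mid`, `old` into
#'   `traj$points`.
#' @export
segment_by_recency <- function(traj, t_now, style = render_style()) {
  ts <- traj$points$timestamp_s
  if (t_now < ts[1]) stop("t_now precedes the first trajectory point")
  age <- t_now - ts
  past <- age >= 0
  list(recent = which(past & age <= style$recent_window_s),
       mid = which(past & age > style$recent_window_s &
                     age <= style$mid_window_s),
       old = which(past & age > style$mid_window_s))
}

# oblique projection of tank coordinates onto the drawing plane
project_oblique <- function(x, y, z, shear = 0.45, angle = pi / 6) {
  list(px = x + shear * cos(angle) * y, py = z + shear * sin(angle) * y)
}

#' Compute the render specification for one animation frame
#'
#' Side-effect-free: returns the segmentation, per-class colors and overlay
#' values ([kinematic_profile()] cumulative distance and instantaneous
#' velocity at `t_now`) without drawing.
#'
#' @inheritParams segment_by_recency
#' @param kin optional precomputed [kinematic_profile()] of `traj`.
#' @return List with `segments`, `colors`, `t_now`, `cumulative_cm`,
#'   `velocity_cm_s`.
#' @export
render_spec <- function(traj, t_now, style = render_style(), kin = NULL) {
  seg <- segment_by_recency(traj, t_now, style)
  if (is.null(kin)) kin <- kinematic_profile(traj)
  at <- max(which(kin$timestamp_s <= t_now + 1e-9))
  list(segments = seg,
       colors = c(recent = style$recent_color, mid = style$mid_color,
                  old = style$old_color),
       t_now = t_now,
       cumulative_cm = kin$cumulative_cm[at],
       velocity_cm_s = kin$velocity_cm_s[at])
}

#' Draw one dynamic 3D trajectory frame
#'
#' Renders the trajectory up to `t_now` on a 3-axis view of the tank (cm
#' units, axes scaled to the tank dimensions) with recency coloring, and —
#' in the upper right corner — the cumulative distance traveled and the
#' instantaneous velocity at `t_now`.
#'
#' @inheritParams render_spec
#' @param tank a [tank_geometry()].
#' @param file optional PNG path; when `NULL`, draws on the current device.
#' @param width_px,height_px PNG size.
#' @return Invisibly, the [render_spec()] that was drawn.
#' @export
render_frame <- function(traj, t_now, tank, style = render_style(),
                         kin = NULL, file = NULL,
                         width_px = 800, height_px = 600) {
  spec <- render_spec(traj, t_now, style, kin)
  if (!is.null(file)) {
    grDevices::png(file, width = width_px, height = height_px)
    on.exit(grDevices::dev.off())
  }
  L <- tank$length_x_cm; W <- tank$width_y_cm; H <- tank$height_z_cm
  corners <- expand.grid(x = c(0, L), y = c(0, W), z = c(0, H))
  pc <- project_oblique(corners$x, corners$y, corners$z)
  graphics::plot(NA, xlim = range(pc$px), ylim = range(pc$py), asp = 1,
                 xlab = "X (cm)  /  Y depth (cm)", ylab = "Z (cm)",
                 main = sprintf("t = %.1f s", t_now))
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(1, 3), c(2, 4),
                 c(5, 7), c(6, 8), c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  graphics::segments(pc$px[edges[, 1]], pc$py[edges[, 1]],
                     pc$px[edges[, 2]], pc$py[edges[, 2]], col = "gray70")
  pts <- traj$points
  pp <- project_oblique(pts$x_cm, pts$y_cm, pts$z_cm)
  draw <- function(idx, col) {
    if (length(idx) == 0) return()
    graphics::lines(pp$px[idx], pp$py[idx], col = col)
    graphics::points(pp$px[idx], pp$py[idx], col = col, pch = 16, cex = 0.4)
  }
  draw(spec$segments$old, spec$colors[["old"]])
  draw(spec$segments$mid, spec$colors[["mid"]])
  draw(spec$segments$recent, spec$colors[["recent"]])
  if (style$show_overlays) {
    graphics::legend("topright", bty = "n", legend = c(
      sprintf("cumulative: %.1f cm", spec$cumulative_cm),
      sprintf("velocity: %.1f cm/s",
              ifelse(is.na(spec$velocity_cm_s), 0, spec$velocity_cm_s))))
  }
  invisible(spec)
}

#' Render a sequence of animation frames to PNG files
#'
#' @inheritParams render_frame
#' @param times vector of `t_now` values, one frame each.
#' @param dir output directory.
#' @return Invisibly, the vector of files written.
#' @export
render_animation <- function(traj, times, tank, dir, style = render_style(),
                             width_px = 800, height_px = 600) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kin <- kinematic_profile(traj)
  files <- file.path(dir, sprintf("frame_%04d.png", seq_along(times)))
  for (i in seq_along(times)) {
    render_frame(traj, times[i], tank, style, kin, file = files[i],
                 width_px = width_px, height_px = height_px)
  }
  invisible(files)
}
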