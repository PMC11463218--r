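# shared fixtures: the bundled 43 x 8 x 14 cm tank viewed by two 1920x1080
# cameras, plus small builders used across test files

geo <- fishtrack3d::example_geometry()
tank <- geo$tank
cams <- geo$cameras

# physical extent of one pixel after the ROI->tank map, per view/axis (cm)
px_extent <- function(cam, tank) {
  r <- cam$roi
  c(u = tank$length_x_cm / (r[3] - r[1]),
    v = fishtrack3d:::v_extent_cm(cam, tank) / (r[4] - r[2]))
}

# detection stream built from a matrix-like spec: one row per detection
make_stream <- function(camera, frame_index, cx, cy, w = 0.05, h = 0.05,
                        confidence = 1, dt = 0.1, frames = NULL) {
  n <- length(frame_index)
  df <- data.frame(camera = camera, frame_index = as.integer(frame_index),
                   timestamp_s = frame_index * dt, class_id = 0L,
                   cx = rep_len(cx, n), cy = rep_len(cy, n),
                   w = rep_len(w, n), h = rep_len(h, n),
                   confidence = rep_len(confidence, n),
                   stringsAsFactors = FALSE)
  fishtrack3d:::new_stream(df, frame_set = if (is.null(frames)) frame_index
                           else frames)
}

# straight-line trajectory helper
make_traj <- function(xyz, dt = 0.1, gaps = NULL, frame_index = NULL) {
  n <- nrow(xyz)
  if (is.null(frame_index)) frame_index <- 0:(n - 1)
  trajectory(data.frame(frame_index = frame_index,
                        timestamp_s = frame_index * dt,
                        x_cm = xyz[, 1], y_cm = xyz[, 2], z_cm = xyz[, 3]),
             dt_s = dt, gaps = gaps)
}
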