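# run code under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Simulator configuration
#'
#' Parameters of the synthetic swim and detector-degradation model. Defaults
#' describe a single adult zebrafish sampled at 10 Hz with a strong
#' surface-layer preference (upper/middle/lower occupancy 57.7 / 17.7 /
#' 24.6 %), mild detector dropout, 2 px localization noise, and occasional
#' near-wall reflection false positives.
#'
#' @param seed integer seed; every random draw flows from it.
#' @param n_frames number of frames (>= 2).
#' @param dt_s sampling interval in seconds (default 0.1, i.e. 10 Hz).
#' @param mean_speed_cm_s mean horizontal swimming speed.
#' @param persistence directional autocorrelation in `[0, 1]`; 1 is the
#'   ballistic limit (fixed heading, specular wall reflections, no layer
#'   steering).
#' @param layer_bias named target occupancy fractions `lower`, `middle`,
#'   `upper`; must sum to 1.
#' @param fish_size_cm named `length`, `height`, `width` of the fish in cm
#'   (sets the projected box extents).
#' @param dropout_p_top,dropout_p_side per-frame probability a view misses
#'   the fish (blur/occlusion).
#' @param noise_px_sd pixel s.d. of detection-center localization noise.
#' @param reflection_p probability of a mirrored false positive when the
#'   fish is within `wall_margin_cm` of a wall of the view plane.
#' @param wall_margin_cm distance from a wall within which reflections can
#'   appear.
#' @param vertical_sd_cm s.d. of the small per-frame vertical move.
#' @param dart_p probability a vertical move is a fast dart.
#' @param dart_sd_cm s.d. of dart moves (bursts of ~tens of cm/s, within a
#'   zebrafish's escape-swim range).
#' @param init_heading initial 3D heading (used by the ballistic limit).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_frames = 1000L, dt_s = 0.1,
                       mean_speed_cm_s = 8, persistence = 0.8,
                       layer_bias = c(lower = 0.246, middle = 0.177,
                                      upper = 0.577),
                       fish_size_cm = c(length = 3.5, height = 0.8,
                                        width = 0.6),
                       dropout_p_top = 0.05, dropout_p_side = 0.05,
                       noise_px_sd = 2, reflection_p = 0.1,
                       wall_margin_cm = 1.5,
                       vertical_sd_cm = 0.6, dart_p = 0.15, dart_sd_cm = 4,
                       init_heading = c(1, 0, 0)) {
  stopifnot(n_frames >= 2, dt_s > 0, mean_speed_cm_s > 0,
            persistence >= 0, persistence <= 1,
            dropout_p_top >= 0, dropout_p_top <= 1,
            dropout_p_side >= 0, dropout_p_side <= 1,
            reflection_p >= 0, reflection_p <= 1,
            noise_px_sd >= 0, wall_margin_cm >= 0,
            length(layer_bias) == 3, all(layer_bias >= 0))
  if (abs(sum(layer_bias) - 1) > 1e-6) stop("layer_bias must sum to 1")
  if (is.null(names(layer_bias))) {
    names(layer_bias) <- c("lower", "middle", "upper")
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 dt_s = dt_s, mean_speed_cm_s = mean_speed_cm_s,
                 persistence = persistence, layer_bias = layer_bias,
                 fish_size_cm = fish_size_cm,
                 dropout_p_top = dropout_p_top,
                 dropout_p_side = dropout_p_side,
                 noise_px_sd = noise_px_sd, reflection_p = reflection_p,
                 wall_margin_cm = wall_margin_cm,
                 vertical_sd_cm = vertical_sd_cm, dart_p = dart_p,
                 dart_sd_cm = dart_sd_cm,
                 init_heading = init_heading / sqrt(sum(init_heading^2))),
            class = "sim_config")
}

# fold a coordinate into [0, L] by specular reflection
fold_reflect <- function(v, L) {
  w <- v %% (2 * L)
  ifelse(w > L, 2 * L - w, w)
}

#' Simulate a ground-truth swim trajectory
#'
#' Horizontal motion is a correlated random walk: the heading angle persists
#' with parameter `persistence`, speed varies around `mean_speed_cm_s`, and
#' walls reflect specularly. Vertical motion is a Metropolis-adjusted random
#' walk (small steps plus occasional darts, reflected at the floor and
#' surface) whose stationary distribution is the piecewise-constant
#' layer-bias density, so long-run layer occupancy converges to
#' `layer_bias`. With `persistence = 1` the walk degenerates to a ballistic
#' straight line with specular reflections (the deterministic limit).
#'
#' @param cfg a [sim_config()].
#' @param tank a [tank_geometry()].
#' @return A [trajectory()] of `n_frames` observed points.
#' @export
simulate_trajectory <- function(cfg, tank) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tank, "tank_geometry"))
  L <- tank$length_x_cm; W <- tank$width_y_cm; H <- tank$height_z_cm
  if (min(L, W, H) <= 0) stop("degenerate tank")
  n <- cfg$n_frames
  dt <- cfg$dt_s
  with_seed(cfg$seed, {
    if (cfg$persistence >= 1) {
      # ballistic limit: fixed heading, specular reflections, closed form
      t <- (0:(n - 1)) * dt
      v <- cfg$init_heading * cfg$mean_speed_cm_s
      start <- c(L, W, H) / 2
      pts <- data.frame(frame_index = 0:(n - 1), timestamp_s = t,
                        x_cm = fold_reflect(start[1] + v[1] * t, L),
                        y_cm = fold_reflect(start[2] + v[2] * t, W),
                        z_cm = fold_reflect(start[3] + v[3] * t, H))
      return(trajectory(pts, dt_s = dt))
    }
    bias <- cfg$layer_bias
    layer_of <- function(z) pmin(floor(z / (H / 3)), 2) + 1
    # start in a layer drawn from the target occupancy to shorten burn-in
    z0_layer <- sample.int(3, 1, prob = bias)
    x <- numeric(n); y <- numeric(n); z <- numeric(n)
    x[1] <- L / 2; y[1] <- W / 2
    z[1] <- (z0_layer - 1) * H / 3 + stats::runif(1) * H / 3
    theta <- atan2(cfg$init_heading[2], cfg$init_heading[1])
    turn <- (1 - cfg$persistence) * stats::runif(n, -pi, pi)
    speed <- abs(stats::rnorm(n, cfg$mean_speed_cm_s,
                              0.3 * cfg$mean_speed_cm_s))
    dart <- stats::runif(n) < cfg$dart_p
    dz <- stats::rnorm(n) * ifelse(dart, cfg$dart_sd_cm, cfg$vertical_sd_cm)
    acc <- stats::runif(n)
    for (i in 2:n) {
      theta <- theta + turn[i]
      xp <- x[i - 1] + cos(theta) * speed[i] * dt
      yp <- y[i - 1] + sin(theta) * speed[i] * dt
      if (xp < 0 || xp > L) {
        xp <- fold_reflect(xp, L)
        theta <- pi - theta
      }
      if (yp < 0 || yp > W) {
        yp <- fold_reflect(yp, W)
        theta <- -theta
      }
      x[i] <- xp; y[i] <- yp
      zp <- fold_reflect(z[i - 1] + dz[i], H)
      ratio <- bias[layer_of(zp)] / bias[layer_of(z[i - 1])]
      z[i] <- if (acc[i] < ratio) zp else z[i - 1]
    }
    trajectory(data.frame(frame_index = 0:(n - 1),
                          timestamp_s = (0:(n - 1)) * dt,
                          x_cm = x, y_cm = y, z_cm = z),
               dt_s = dt)
  })
}

#' Project a ground-truth trajectory into ideal per-view detection boxes
#'
#' Inverse of the pixel-to-tank calibration: each 3D point becomes a
#' normalized YOLO box centered on the projected pixel in each view, with
#' extents given by the fish size (top view: length x width; side view:
#' length x height) and confidence 1.
#'
#' @param truth a [trajectory()].
#' @param cameras named list of `top` and `side` [camera_config()]s.
#' @param tank a [tank_geometry()].
#' @param fish_size_cm named `length`, `height`, `width` in cm.
#' @return Named list `top`, `side` of per-frame ground-truth box data
#'   frames (detection-stream columns, confidence 1).
#' @export
project_to_views <- function(truth, cameras, tank,
                             fish_size_cm = c(length = 3.5, height = 0.8,
                                              width = 0.6)) {
  pts <- truth$points
  one_view <- function(cam) {
    b <- if (cam$view == "top") pts$y_cm else pts$z_cm
    uv <- tank_to_px(data.frame(a_cm = pts$x_cm, b_cm = b), cam, tank)
    r <- cam$roi
    px_per_cm_u <- (r[3] - r[1]) / tank$length_x_cm
    px_per_cm_v <- (r[4] - r[2]) / v_extent_cm(cam, tank)
    ext_v_cm <- if (cam$view == "top") fish_size_cm[["width"]] else
      fish_size_cm[["height"]]
    w <- fish_size_cm[["length"]] * px_per_cm_u / cam$image_w_px
    h <- ext_v_cm * px_per_cm_v / cam$image_h_px
    cx <- uv$u / cam$image_w_px
    cy <- uv$v / cam$image_h_px
    # keep the whole box inside the image near the walls
    cx <- pmin(pmax(cx, w / 2), 1 - w / 2)
    cy <- pmin(pmax(cy, h / 2), 1 - h / 2)
    new_stream(data.frame(camera = cam$view, frame_index = pts$frame_index,
                          timestamp_s = pts$timestamp_s, class_id = 0L,
                          cx = cx, cy = cy, w = w, h = h, confidence = 1,
                          stringsAsFactors = FALSE),
               frame_set = pts$frame_index)
  }
  list(top = one_view(cameras$top), side = one_view(cameras$side))
}

#' Degrade an ideal box stream into a realistic detection stream
#'
#' Per frame, independently: with the view's dropout probability the
#' detection is omitted (a missed, blurred frame); otherwise its center is
#' jittered by Gaussian pixel noise and its confidence drawn from Beta(20, 1)
#' (mass near 1). When the true position lies within `wall_margin_cm` of a
#' wall of the view plane, a mirrored false positive is appended with
#' probability `reflection_p`, reflected across the nearest ROI edge in
#' pixel space with a mid-range Beta(4, 2) confidence — emulating surface
#' and wall reflections that detectors misread as the animal.
#'
#' @param truth_boxes one view's ideal boxes from [project_to_views()].
#' @param cfg a [sim_config()].
#' @param view `"top"` or `"side"`.
#' @param cam that view's [camera_config()].
#' @param tank a [tank_geometry()].
#' @param seed RNG seed; defaults to `cfg$seed + 1` (top) / `cfg$seed + 2`
#'   (side) so the two views degrade independently but reproducibly.
#' @return A detection stream covering every input frame.
#' @export
corrupt_stream <- function(truth_boxes, cfg, view = c("top", "side"),
                           cam, tank, seed = NULL) {
  view <- match.arg(view)
  if (is.null(seed)) seed <- cfg$seed + if (view == "top") 1L else 2L
  drop_p <- if (view == "top") cfg$dropout_p_top else cfg$dropout_p_side
  tb <- as.data.frame(truth_boxes)
  n <- nrow(tb)
  with_seed(seed, {
    kept <- stats::runif(n) >= drop_p
    det <- tb[kept, , drop = FALSE]
    m <- nrow(det)
    if (m > 0) {
      det$cx <- pmin(pmax(det$cx + stats::rnorm(m, 0, cfg$noise_px_sd) /
                            cam$image_w_px, det$w / 2), 1 - det$w / 2)
      det$cy <- pmin(pmax(det$cy + stats::rnorm(m, 0, cfg$noise_px_sd) /
                            cam$image_h_px, det$h / 2), 1 - det$h / 2)
      det$confidence <- stats::rbeta(m, 20, 1)
    }
    refl <- reflection_fps(tb, cfg, cam, tank)
    out <- rbind(det, refl)
    out <- out[order(out$frame_index, -out$confidence + 0), , drop = FALSE]
    rownames(out) <- NULL
    new_stream(out, frame_set = tb$frame_index)
  })
}

# mirrored near-wall false positives for one view
reflection_fps <- function(tb, cfg, cam, tank) {
  if (cfg$reflection_p <= 0 || nrow(tb) == 0) return(tb[0, , drop = FALSE])
  r <- cam$roi
  ext_b <- v_extent_cm(cam, tank)
  # true planar position in cm, from the uncorrupted box center
  a <- tb$cx * cam$image_w_px
  b <- tb$cy * cam$image_h_px
  fu <- (pmin(pmax(a, r[1]), r[3]) - r[1]) / (r[3] - r[1])
  fv <- (pmin(pmax(b, r[2]), r[4]) - r[2]) / (r[4] - r[2])
  if (cam$flip_v) fv <- 1 - fv
  a_cm <- fu * tank$length_x_cm
  b_cm <- fv * ext_b
  d_edges <- cbind(a_cm, tank$length_x_cm - a_cm, b_cm, ext_b - b_cm)
  nearest <- max.col(-d_edges, ties.method = "first")
  near_wall <- d_edges[cbind(seq_len(nrow(tb)), nearest)] <= cfg$wall_margin_cm
  fire <- near_wall & stats::runif(nrow(tb)) < cfg$reflection_p
  if (!any(fire)) return(tb[0, , drop = FALSE])
  fp <- tb[fire, , drop = FALSE]
  edge <- nearest[fire]
  u <- fp$cx * cam$image_w_px
  v <- fp$cy * cam$image_h_px
  # mirror across the nearest roi edge in pixel space
  u <- ifelse(edge == 1, 2 * r[1] - u, ifelse(edge == 2, 2 * r[3] - u, u))
  is_v_lo_edge <- if (cam$flip_v) 4L else 3L
  v <- ifelse(edge == is_v_lo_edge, 2 * r[2] - v,
              ifelse(edge %in% c(3L, 4L), 2 * r[4] - v, v))
  fp$cx <- pmin(pmax(u / cam$image_w_px, fp$w / 2), 1 - fp$w / 2)
  fp$cy <- pmin(pmax(v / cam$image_h_px, fp$h / 2), 1 - fp$h / 2)
  fp$confidence <- stats::rbeta(nrow(fp), 4, 2)
  fp
}

#' Run the full simulator: truth, ideal boxes, degraded streams
#'
#' @param cfg a [sim_config()].
#' @param geometry a geometry list (see [read_geometry_config()]); defaults
#'   to [example_geometry()].
#' @return An object of class `sim_output`: list with `truth` (trajectory),
#'   `truth_boxes` (ideal per-view boxes), `top_stream`, `side_stream`
#'   (degraded detection streams), `geometry` and `config`.
#' @export
simulate_dataset <- function(cfg, geometry = example_geometry()) {
  tank <- geometry$tank
  cams <- geometry$cameras
  truth <- simulate_trajectory(cfg, tank)
  boxes <- project_to_views(truth, cams, tank, cfg$fish_size_cm)
  structure(list(
    truth = truth,
    truth_boxes = boxes,
    top_stream = corrupt_stream(boxes$top, cfg, "top", cams$top, tank),
    side_stream = corrupt_stream(boxes$side, cfg, "side", cams$side, tank),
    geometry = geometry, config = cfg),
    class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d frames at %g Hz\n",
              x$config$n_frames, 1 / x$config$dt_s))
  cat(sprintf("  top detections: %d   side detections: %d\n",
              nrow(x$top_stream), nrow(x$side_stream)))
  invisible(x)
}
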