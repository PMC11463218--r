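#' Tank geometry
#'
#' Physical dimensions of the box-shaped tank. The coordinate convention is:
#' origin at the viewer's left-front-bottom corner, X along the tank length
#' (the axis both cameras share), Y along the width, Z up toward the water
#' surface.
#'
#' @param length_x_cm,width_y_cm,height_z_cm positive dimensions in cm.
#' @return An object of class `tank_geometry`.
#' @export
tank_geometry <- function(length_x_cm, width_y_cm, height_z_cm) {
  dims <- c(length_x_cm, width_y_cm, height_z_cm)
  if (!is.numeric(dims) || length(dims) != 3 || any(!is.finite(dims)) ||
      any(dims <= 0)) {
    stop("tank dimensions must be three positive finite numbers")
  }
  structure(list(length_x_cm = length_x_cm, width_y_cm = width_y_cm,
                 height_z_cm = height_z_cm),
            class = "tank_geometry")
}

#' Camera configuration
#'
#' Describes how one camera view maps pixels to tank axes. The top view's
#' image axes (u, v) correspond to tank (X, Y); the side view's to (X, Z).
#' `roi` is the pixel rectangle `(x0, y0, x1, y1)` that frames the tank in
#' the image. Image v runs downward, so `flip_v = TRUE` (the side-view
#' default) makes the physical coordinate grow toward the image top — Z
#' increases toward the water surface.
#'
#' @param view `"top"` or `"side"`.
#' @param image_w_px,image_h_px positive integer image size.
#' @param roi numeric `c(x0, y0, x1, y1)` with `x0 < x1`, `y0 < y1`, inside
#'   the image.
#' @param flip_v invert the image v axis; defaults to `TRUE` for the side
#'   view, `FALSE` for the top view.
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(view = c("top", "side"), image_w_px, image_h_px,
                          roi, flip_v = NULL) {
  view <- match.arg(view)
  stopifnot(image_w_px > 0, image_h_px > 0, length(roi) == 4)
  roi <- as.numeric(roi)
  if (!(roi[1] < roi[3] && roi[2] < roi[4])) stop("roi must have x0<x1, y0<y1")
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > image_w_px || roi[4] > image_h_px) {
    stop("roi must lie within the image bounds")
  }
  if (is.null(flip_v)) flip_v <- identical(view, "side")
  structure(list(view = view, image_w_px = as.integer(image_w_px),
                 image_h_px = as.integer(image_h_px), roi = roi,
                 flip_v = isTRUE(flip_v)),
            class = "camera_config")
}

# which tank dimension the view's v axis spans
v_extent_cm <- function(cam, tank) {
  if (cam$view == "top") tank$width_y_cm else tank$height_z_cm
}

#' Detection-box center in pixels
#'
#' The box center is used as the animal's coordinate point in each view.
#'
#' @param det detection rows (`cx`, `cy` normalized to the full image).
#' @param cam a [camera_config()].
#' @return Data frame with columns `u`, `v` in pixels (one row per detection).
#' @export
bbox_center_px <- function(det, cam) {
  data.frame(u = det$cx * cam$image_w_px, v = det$cy * cam$image_h_px)
}

#' Map pixel points into tank coordinates for one view
#'
#' A pure affine (proportional) map of the ROI rectangle onto the physical
#' plane of the view: `a_cm` spans the tank length along X and `b_cm` the
#' matching dimension (top: Y width, side: Z height). Points up to `slack_px`
#' outside the ROI are clamped onto it; farther out is an error.
#'
#' @param p data frame (or 2-vector) of pixel points `u`, `v`.
#' @param cam a [camera_config()].
#' @param tank a [tank_geometry()].
#' @param slack_px pixels of tolerance outside the ROI before erroring.
#' @return Data frame with `view`, `a_cm`, `b_cm`.
#' @export
px_to_tank <- function(p, cam, tank, slack_px = 2) {
  if (!is.data.frame(p)) p <- data.frame(u = p[1], v = p[2])
  r <- cam$roi
  out_u <- pmax(r[1] - p$u, p$u - r[3], 0)
  out_v <- pmax(r[2] - p$v, p$v - r[4], 0)
  bad <- which(out_u > slack_px | out_v > slack_px)
  if (length(bad)) {
    stop(sprintf("pixel point (%.2f, %.2f) outside roi beyond %g px slack",
                 p$u[bad[1]], p$v[bad[1]], slack_px))
  }
  u <- pmin(pmax(p$u, r[1]), r[3])
  v <- pmin(pmax(p$v, r[2]), r[4])
  fu <- (u - r[1]) / (r[3] - r[1])
  fv <- (v - r[2]) / (r[4] - r[2])
  if (cam$flip_v) fv <- 1 - fv
  data.frame(view = cam$view,
             a_cm = fu * tank$length_x_cm,
             b_cm = fv * v_extent_cm(cam, tank),
             stringsAsFactors = FALSE)
}

#' Inverse of [px_to_tank()]: tank-plane coordinates to pixels
#'
#' @param ab data frame with `a_cm`, `b_cm` (or a 2-vector).
#' @inheritParams px_to_tank
#' @return Data frame with `u`, `v` in pixels.
#' @export
tank_to_px <- function(ab, cam, tank) {
  if (!is.data.frame(ab)) ab <- data.frame(a_cm = ab[1], b_cm = ab[2])
  r <- cam$roi
  fu <- ab$a_cm / tank$length_x_cm
  fv <- ab$b_cm / v_extent_cm(cam, tank)
  if (cam$flip_v) fv <- 1 - fv
  data.frame(u = r[1] + fu * (r[3] - r[1]),
             v = r[2] + fv * (r[4] - r[2]))
}

#' Read or write a geometry configuration file
#'
#' YAML schema: `tank: {length_x_cm, width_y_cm, height_z_cm}`, `dt_s`, and a
#' `cameras` block with `top` and `side` entries each holding `image_w_px`,
#' `image_h_px`, `roi` (x0, y0, x1, y1) and optional `flip_v`.
#'
#' @param path YAML file path.
#' @return A list with `tank` ([tank_geometry()]), `cameras` (named list of
#'   [camera_config()]), and `dt_s`.
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tank) || is.null(cfg$cameras)) {
    stop("geometry config needs 'tank' and 'cameras' blocks")
  }
  tank <- tank_geometry(cfg$tank$length_x_cm, cfg$tank$width_y_cm,
                        cfg$tank$height_z_cm)
  cams <- lapply(c(top = "top", side = "side"), function(v) {
    c0 <- cfg$cameras[[v]]
    if (is.null(c0)) stop("geometry config missing camera '", v, "'")
    camera_config(v, c0$image_w_px, c0$image_h_px, unlist(c0$roi), c0$flip_v)
  })
  list(tank = tank, cameras = cams,
       dt_s = if (is.null(cfg$dt_s)) 0.1 else cfg$dt_s)
}

#' @rdname read_geometry_config
#' @param geometry a list as returned by [read_geometry_config()].
#' @export
write_geometry_config <- function(geometry, path) {
  cams <- lapply(geometry$cameras, function(cam) {
    list(image_w_px = cam$image_w_px, image_h_px = cam$image_h_px,
         roi = as.list(cam$roi), flip_v = cam$flip_v)
  })
  yaml::write_yaml(list(tank = unclass(geometry$tank),
                        dt_s = geometry$dt_s,
                        cameras = cams), path)
  invisible(path)
}

#' Bundled example geometry
#'
#' A 43 x 8 x 14 cm acrylic tank imaged by two 1920x1080 cameras with
#' documented ROIs; dt 0.1 s (10 Hz sampling).
#'
#' @return A geometry list (see [read_geometry_config()]).
#' @export
example_geometry <- function() {
  list(tank = tank_geometry(43, 8, 14),
       cameras = list(
         top = camera_config("top", 1920, 1080, c(160, 340, 1760, 740)),
         side = camera_config("side", 1920, 1080, c(160, 140, 1760, 940))),
       dt_s = 0.1)
}
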