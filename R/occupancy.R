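#' Assign trajectory points to the 3x3x3 tank regions
#'
#' Each tank axis is split into three equal intervals, giving 27 regions.
#' Region ids run 1..27 with x varying fastest, then y, then z bottom-up:
#' `id = iz*9 + iy*3 + ix + 1` where `ix`, `iy`, `iz` are the 0-based
#' interval indices. Interval edges are half-open `[lo, hi)` except the last
#' interval of each axis, which is closed so tank-boundary points are
#' classifiable. Points up to `slack_cm` outside the tank are clamped onto
#' it; farther out is an error.
#'
#' @param points data frame with `x_cm`, `y_cm`, `z_cm` (a [trajectory()] is
#'   also accepted).
#' @param tank a [tank_geometry()].
#' @param slack_cm out-of-tank tolerance before erroring.
#' @return Integer vector of region ids in 1..27.
#' @export
assign_region <- function(points, tank, slack_cm = 0.1) {
  if (inherits(points, "fish_trajectory")) points <- points$points
  axis_bin <- function(v, extent, axis) {
    if (any(v < -slack_cm | v > extent + slack_cm)) {
      bad <- v[v < -slack_cm | v > extent + slack_cm][1]
      stop(sprintf("%s coordinate %.3f cm beyond tank bounds (+/- %g cm slack)",
                   axis, bad, slack_cm))
    }
    v <- pmin(pmax(v, 0), extent)
    pmin(floor(v / (extent / 3)), 2L)
  }
  ix <- axis_bin(points$x_cm, tank$length_x_cm, "x")
  iy <- axis_bin(points$y_cm, tank$width_y_cm, "y")
  iz <- axis_bin(points$z_cm, tank$height_z_cm, "z")
  as.integer(iz * 9L + iy * 3L + ix + 1L)
}

#' Region occupancy histogram
#'
#' Counts and proportions of points per 3x3x3 region.
#'
#' @inheritParams assign_region
#' @return A `region_grid`: data frame `region_id`, `ix`, `iy`, `iz`,
#'   `count`, `proportion` (27 rows), with attribute `total`.
#' @export
region_histogram <- function(points, tank, slack_cm = 0.1) {
  if (inherits(points, "fish_trajectory")) points <- points$points
  if (nrow(points) == 0) stop("region_histogram needs at least one point")
  ids <- assign_region(points, tank, slack_cm)
  region_grid(tabulate(ids, nbins = 27L))
}

#' Build a region grid from 27 counts
#'
#' @param counts integer vector of 27 non-negative counts in region-id order.
#' @return A `region_grid` (see [region_histogram()]).
#' @export
region_grid <- function(counts) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 27, all(counts >= 0), sum(counts) > 0)
  id <- 1:27
  g <- data.frame(region_id = id,
                  ix = (id - 1L) %% 3L,
                  iy = ((id - 1L) %/% 3L) %% 3L,
                  iz = (id - 1L) %/% 9L,
                  count = counts,
                  proportion = counts / sum(counts))
  structure(g, total = sum(counts), class = c("region_grid", "data.frame"))
}

#' Layer totals and proportions
#'
#' Aggregates the 27 regions into the lower, middle and upper thirds of the
#' water column (iz = 0, 1, 2). Percentages are computed from the counts and
#' rounded to 2 decimals for display.
#'
#' @param grid a `region_grid`, or an integer vector of 3 layer counts
#'   (lower, middle, upper).
#' @return Data frame `layer`, `count`, `pct` ordered lower, middle, upper.
#' @export
layer_summary <- function(grid) {
  counts <- if (inherits(grid, "region_grid")) {
    as.integer(tapply(grid$count, grid$iz, sum))
  } else {
    stopifnot(length(grid) == 3, all(grid >= 0))
    as.integer(grid)
  }
  data.frame(layer = c("lower", "middle", "upper"),
             count = counts,
             pct = round(counts / sum(counts) * 100, 2),
             stringsAsFactors = FALSE)
}

#' Heatmap encoding of a region grid
#'
#' One record per region for the 3D bubble heatmap: circle center at the
#' region's physical midpoint, radius linear in the region's proportion, and
#' color ramping from dark blue (smallest proportion) to bright green
#' (largest).
#'
#' @param grid a `region_grid`.
#' @param tank a [tank_geometry()] giving the physical centers.
#' @param max_radius_cm radius drawn for the largest proportion.
#' @param low_color,high_color ends of the color ramp.
#' @return Data frame `region_id`, `x_cm`, `y_cm`, `z_cm`, `proportion`,
#'   `radius_cm`, `color`.
#' @export
heatmap_spec <- function(grid, tank = tank_geometry(43, 8, 14),
                         max_radius_cm = 2,
                         low_color = "#00008B", high_color = "#00E65C") {
  stopifnot(inherits(grid, "region_grid"))
  p <- grid$proportion
  pmaxv <- max(p)
  radius <- if (pmaxv > 0) p / pmaxv * max_radius_cm else rep(0, 27)
  t <- if (diff(range(p)) > 0) (p - min(p)) / diff(range(p)) else rep(1, 27)
  ramp <- grDevices::colorRamp(c(low_color, high_color))
  cols <- grDevices::rgb(ramp(t), maxColorValue = 255)
  data.frame(region_id = grid$region_id,
             x_cm = (grid$ix + 0.5) * tank$length_x_cm / 3,
             y_cm = (grid$iy + 0.5) * tank$width_y_cm / 3,
             z_cm = (grid$iz + 0.5) * tank$height_z_cm / 3,
             proportion = p, radius_cm = radius, color = cols,
             stringsAsFactors = FALSE)
}

#' Write region and layer reports
#'
#' @param grid a `region_grid`.
#' @param region_path CSV for `region_id,ix,iy,iz,count,proportion`.
#' @param layer_path CSV for `layer,count,pct`.
#' @return Invisibly, `region_path`.
#' @export
write_occupancy_csv <- function(grid, region_path, layer_path = NULL) {
  utils::write.csv(as.data.frame(grid), region_path, row.names = FALSE)
  if (!is.null(layer_path)) {
    utils::write.csv(layer_summary(grid), layer_path, row.names = FALSE)
  }
  invisible(region_path)
}
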