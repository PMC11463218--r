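#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are in center form `(cx, cy, w, h)` (any consistent units).
#' Disjoint boxes — and the degenerate case of two zero-area boxes — score 0.
#'
#' @param a,b numeric vectors `c(cx, cy, w, h)` or one-row data frames with
#'   those columns.
#' @return Overlap area divided by union area, in `[0, 1]`.
#' @export
iou <- function(a, b) {
  as_box <- function(x) {
    if (is.data.frame(x)) x <- c(x$cx[1], x$cy[1], x$w[1], x$h[1])
    x
  }
  a <- as_box(a); b <- as_box(b)
  stopifnot(a[3] >= 0, a[4] >= 0, b[3] >= 0, b[4] >= 0)
  ix <- min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
    max(a[1] - a[3] / 2, b[1] - b[3] / 2)
  iy <- min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
    max(a[2] - a[4] / 2, b[2] - b[4] / 2)
  inter <- max(ix, 0) * max(iy, 0)
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

#' Confusion counts
#'
#' Frame-level true/false positive/negative tallies feeding accuracy,
#' precision and recall.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

add_counts <- function(a, b) {
  confusion_counts(a$tp + b$tp, a$fp + b$fp, a$tn + b$tn, a$fn + b$fn)
}

#' Score one frame's detections against ground truth
#'
#' Detections are confidence-filtered, then greedily matched to ground-truth
#' boxes by best IoU. A matched pair with IoU at or above `iou_thr` is a true
#' positive; unmatched detections are false positives; unmatched truths are
#' false negatives. A frame with no truth and no (surviving) detection is one
#' true negative.
#'
#' @param dets detection rows for one frame (needs `cx,cy,w,h,confidence`).
#' @param truth ground-truth boxes for the frame (`cx,cy,w,h`), 0+ rows.
#' @param iou_thr IoU threshold for a match (default 0.5).
#' @param conf_thr confidence threshold applied to `dets`.
#' @return A [confusion_counts()] increment for the frame.
#' @export
match_frame <- function(dets, truth, iou_thr = 0.5, conf_thr = 0) {
  dets <- dets[dets$confidence >= conf_thr, , drop = FALSE]
  nd <- nrow(dets); nt <- nrow(truth)
  if (nd == 0 && nt == 0) return(confusion_counts(tn = 1))
  if (nt == 0) return(confusion_counts(fp = nd))
  if (nd == 0) return(confusion_counts(fn = nt))
  m <- matrix(0, nd, nt)
  for (i in seq_len(nd)) {
    for (j in seq_len(nt)) m[i, j] <- iou(dets[i, ], truth[j, ])
  }
  tp <- 0L
  repeat {
    best <- which.max(m)
    if (m[best] < iou_thr) break
    bi <- (best - 1) %% nd + 1
    bj <- (best - 1) %/% nd + 1
    tp <- tp + 1L
    m[bi, ] <- -1
    m[, bj] <- -1
    if (all(m < iou_thr)) break
  }
  confusion_counts(tp = tp, fp = nd - tp, fn = nt - tp)
}

#' Score whole detection streams against per-frame truth boxes
#'
#' Sums [match_frame()] over the union of frames in the stream and the truth
#' set.
#'
#' @param stream a detection stream.
#' @param truth_boxes data frame of ground-truth boxes with `frame_index`
#'   plus `cx,cy,w,h` (as produced by [project_to_views()]).
#' @inheritParams match_frame
#' @return Total [confusion_counts()].
#' @export
match_streams <- function(stream, truth_boxes, iou_thr = 0.5, conf_thr = 0) {
  frames <- sort(union(frame_set(stream), truth_boxes$frame_index))
  total <- confusion_counts()
  for (f in frames) {
    total <- add_counts(total, match_frame(
      stream[stream$frame_index == f, , drop = FALSE],
      truth_boxes[truth_boxes$frame_index == f, , drop = FALSE],
      iou_thr, conf_thr))
  }
  total
}

#' Accuracy, precision and recall from confusion counts
#'
#' accuracy = (tp+tn)/(tp+fp+tn+fn); precision = tp/(tp+fp);
#' recall = tp/(tp+fn). A metric whose denominator is zero is reported as
#' `NA` (undefined), never coerced to 0 or 1.
#'
#' @param counts a [confusion_counts()].
#' @return Data frame with `accuracy`, `precision`, `recall` as fractions.
#' @export
metrics <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  data.frame(accuracy = (counts$tp + counts$tn) / n,
             precision = safe_div(counts$tp, counts$tp + counts$fp),
             recall = safe_div(counts$tp, counts$tp + counts$fn))
}

#' Coordinate-error statistics against ground truth
#'
#' Frames present in both series are compared by 3D Euclidean distance;
#' `n_detected` is the number of matched frames and max/min/mean summarize
#' the per-frame errors.
#'
#' @param est estimated points (a [trajectory()] or data frame with
#'   `frame_index`, `x_cm`, `y_cm`, `z_cm`).
#' @param truth ground-truth points in the same form.
#' @return An object of class `error_stats` with `n_detected`, `max_err_cm`,
#'   `min_err_cm`, `mean_err_cm`.
#' @export
error_stats <- function(est, truth) {
  if (inherits(est, "fish_trajectory")) est <- est$points
  if (inherits(truth, "fish_trajectory")) truth <- truth$points
  common <- intersect(est$frame_index, truth$frame_index)
  if (length(common) == 0) stop("no frames present in both series")
  e <- est[match(common, est$frame_index), ]
  t <- truth[match(common, truth$frame_index), ]
  d <- euclidean_distance(e, t)
  structure(list(n_detected = length(common),
                 max_err_cm = max(d), min_err_cm = min(d),
                 mean_err_cm = mean(d)),
            class = "error_stats")
}

#' @rdname error_stats
#' @param n_detected,max_err_cm,min_err_cm,mean_err_cm build an
#'   `error_stats` directly from published summary numbers.
#' @export
error_stats_from_summary <- function(n_detected, max_err_cm, min_err_cm,
                                     mean_err_cm) {
  stopifnot(n_detected >= 1)
  if (min_err_cm > max_err_cm) stop("min error exceeds max error")
  # published summaries are accepted as printed; only min <= max is enforced,
  # since computed stats always satisfy min <= mean <= max but printed ones
  # may not
  structure(list(n_detected = as.integer(n_detected),
                 max_err_cm = max_err_cm, min_err_cm = min_err_cm,
                 mean_err_cm = mean_err_cm),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("n=%d  err max %.3f / min %.3f / mean %.3f cm\n",
              x$n_detected, x$max_err_cm, x$min_err_cm, x$mean_err_cm))
  invisible(x)
}

#' Percent-change comparison between two models' error statistics
#'
#' Signed percent changes from `initial` to `final`:
#' `(final - initial) / initial * 100` for the detected-coordinate count and
#' for each error statistic (negative = improvement). Full precision is
#' retained; the print method rounds to 2 decimals. A zero initial statistic
#' yields `NA` (undefined change).
#'
#' @param initial,final [error_stats()] objects.
#' @return An object of class `model_comparison` with `coord_pct_change`,
#'   `max_err_pct_change`, `min_err_pct_change`, `mean_err_pct_change`.
#' @export
compare_models <- function(initial, final) {
  pct <- function(a, b) if (a == 0) NA_real_ else (b - a) / a * 100
  structure(list(
    coord_pct_change = pct(initial$n_detected, final$n_detected),
    max_err_pct_change = pct(initial$max_err_cm, final$max_err_cm),
    min_err_pct_change = pct(initial$min_err_cm, final$min_err_cm),
    mean_err_pct_change = pct(initial$mean_err_cm, final$mean_err_cm)),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%+.2f%%", v)
  cat("coordinates:", fmt(x$coord_pct_change), "\n")
  cat("max error:  ", fmt(x$max_err_pct_change), "\n")
  cat("min error:  ", fmt(x$min_err_pct_change), "\n")
  cat("mean error: ", fmt(x$mean_err_pct_change), "\n")
  invisible(x)
}

#' Write a JSON evaluation report
#'
#' @param counts a [confusion_counts()] or `NULL`.
#' @param stats an [error_stats()] or `NULL`.
#' @param comparison a [compare_models()] result or `NULL`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_json <- function(path, counts = NULL, stats = NULL,
                                  comparison = NULL) {
  report <- list()
  if (!is.null(counts)) {
    report$confusion <- unclass(counts)
    report$metrics <- as.list(metrics(counts))
  }
  if (!is.null(stats)) report$error_stats <- unclass(stats)
  if (!is.null(comparison)) report$comparison <- unclass(comparison)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
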