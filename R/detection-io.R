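# Detection streams are plain data.frames, one row per detection, with the
# frame universe (including empty frames) kept in attr "frame_set".
# Frame indexing is 0-based; timestamps are always frame_index * dt.

STREAM_COLS <- c("camera", "frame_index", "timestamp_s", "class_id",
                 "cx", "cy", "w", "h", "confidence")

new_stream <- function(df, frame_set) {
  df <- df[, STREAM_COLS, drop = FALSE]
  attr(df, "frame_set") <- sort(unique(as.integer(frame_set)))
  class(df) <- c("detection_stream", "data.frame")
  df
}

empty_stream_df <- function() {
  data.frame(camera = character(), frame_index = integer(),
             timestamp_s = numeric(), class_id = integer(),
             cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
             confidence = numeric(), stringsAsFactors = FALSE)
}

#' Frames covered by a detection stream
#'
#' @param stream a detection stream data frame.
#' @return Sorted integer vector of 0-based frame indices the stream covers,
#'   including frames with zero detections.
#' @export
frame_set <- function(stream) {
  fs <- attr(stream, "frame_set")
  if (is.null(fs)) sort(unique(as.integer(stream$frame_index))) else fs
}

#' Parse one YOLO darknet txt annotation frame
#'
#' Each non-empty line is `class cx cy w h [conf]` with coordinates normalized
#' to the image. A five-field line is ground-truth style and gets confidence
#' 1.0. An empty file is a legal missed frame (zero detections).
#'
#' @param text character: the file content (single string or vector of lines).
#' @param camera `"top"` or `"side"`.
#' @param frame_index 0-based frame number.
#' @param dt sampling interval in seconds; the frame timestamp is
#'   `frame_index * dt`.
#' @param tol numeric tolerance applied before range checks, so values like
#'   1 + 1e-9 from rounded writers still parse.
#' @return A one-frame detection stream (0 or more rows).
#' @export
parse_yolo_frame <- function(text, camera = c("top", "side"), frame_index = 0L,
                             dt = 0.1, tol = 1e-6) {
  camera <- match.arg(camera)
  frame_index <- as.integer(frame_index)
  stopifnot(frame_index >= 0L, dt > 0)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- nzchar(trimws(lines))
  ts <- frame_index * dt
  if (!any(keep)) {
    return(new_stream(empty_stream_df(), frame_set = frame_index))
  }
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!(length(fields) %in% c(5L, 6L))) {
      stop(sprintf("line %d: expected 5 or 6 fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric field '%s'",
                   i, fields[which(is.na(vals))[1]]), call. = FALSE)
    }
    conf <- if (length(vals) == 6L) vals[6] else 1.0
    box <- vals[2:5]
    if (any(box < -tol | box > 1 + tol) || conf < -tol || conf > 1 + tol) {
      stop(sprintf("line %d: normalized value out of [0,1]", i), call. = FALSE)
    }
    box <- pmin(pmax(box, 0), 1)
    # the box itself must fit in the image, not just its center
    if (box[1] - box[3] / 2 < -tol || box[1] + box[3] / 2 > 1 + tol ||
        box[2] - box[4] / 2 < -tol || box[2] + box[4] / 2 > 1 + tol) {
      stop(sprintf("line %d: box extends outside the image", i), call. = FALSE)
    }
    data.frame(camera = camera, frame_index = frame_index, timestamp_s = ts,
               class_id = as.integer(vals[1]), cx = box[1], cy = box[2],
               w = box[3], h = box[4],
               confidence = min(max(conf, 0), 1),
               stringsAsFactors = FALSE)
  })
  new_stream(do.call(rbind, rows), frame_set = frame_index)
}

#' Format detections as YOLO txt lines
#'
#' @param dets detection rows (any data frame with `class_id`, `cx`, `cy`,
#'   `w`, `h`, `confidence`).
#' @param with_conf include the confidence as a sixth field.
#' @param digits decimal places written (default 6).
#' @return Character vector of lines (length 0 for an empty frame).
#' @export
format_yolo <- function(dets, with_conf = TRUE, digits = 6) {
  if (nrow(dets) == 0) return(character())
  fmt <- paste0("%.", digits, "f")
  base <- paste(dets$class_id, sprintf(fmt, dets$cx), sprintf(fmt, dets$cy),
                sprintf(fmt, dets$w), sprintf(fmt, dets$h))
  if (with_conf) paste(base, sprintf(fmt, dets$confidence)) else base
}

#' Read a directory of per-frame YOLO txt files into a detection stream
#'
#' The 0-based frame index is parsed from the trailing digits of each file
#' name stem (e.g. `frame_000017.txt` is frame 17). Empty files are missed
#' frames and still count toward the stream's frame set.
#'
#' @inheritParams parse_yolo_frame
#' @param dir directory containing `.txt` files.
#' @return A detection stream covering every file's frame.
#' @export
read_yolo_dir <- function(dir, camera = c("top", "side"), dt = 0.1) {
  camera <- match.arg(camera)
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop("no .txt files in ", dir)
  stems <- sub("\\.txt$", "", basename(files))
  m <- regmatches(stems, regexpr("[0-9]+$", stems))
  if (length(m) != length(files)) {
    stop("file name without a numeric frame suffix in ", dir)
  }
  idx <- as.integer(m)
  if (anyDuplicated(idx)) {
    stop("duplicate frame index ", idx[duplicated(idx)][1], " in ", dir)
  }
  ord <- order(idx)
  frames <- lapply(ord, function(i) {
    parse_yolo_frame(readLines(files[i], warn = FALSE), camera, idx[i], dt)
  })
  new_stream(do.call(rbind, c(list(empty_stream_df()), frames)),
             frame_set = idx)
}

#' Write a detection stream as one YOLO txt file per frame
#'
#' @param stream a detection stream.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; files are `<prefix><index>.txt`.
#' @param with_conf,digits passed to [format_yolo()].
#' @return Invisibly, the vector of paths written.
#' @export
write_yolo_dir <- function(stream, dir, prefix = "frame_", with_conf = TRUE,
                           digits = 6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- frame_set(stream)
  width <- max(6, nchar(max(c(fs, 0))))
  paths <- file.path(dir, sprintf("%s%0*d.txt", prefix, width, fs))
  by_frame <- split(seq_len(nrow(stream)), factor(stream$frame_index, levels = fs))
  for (k in seq_along(fs)) {
    writeLines(format_yolo(stream[by_frame[[k]], , drop = FALSE],
                           with_conf = with_conf, digits = digits),
               paths[k])
  }
  invisible(paths)
}

#' Read/write a consolidated detection-stream CSV
#'
#' Columns: `camera,frame_index,timestamp_s,class_id,cx,cy,w,h,confidence`.
#' Because empty frames have no rows, the frame set of a stream read from CSV
#' can be widened with `frames`.
#'
#' @param path CSV file path.
#' @param frames optional integer vector of all frame indices the stream
#'   covers (defaults to the indices present in the file).
#' @return A detection stream.
#' @export
read_detection_csv <- function(path, frames = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STREAM_COLS, names(df))
  if (length(missing_cols)) {
    stop("detection CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$frame_index <- as.integer(df$frame_index)
  new_stream(df, frame_set = if (is.null(frames)) df$frame_index else frames)
}

#' @rdname read_detection_csv
#' @param stream a detection stream to write.
#' @export
write_detection_csv <- function(stream, path) {
  utils::write.csv(as.data.frame(stream)[, STREAM_COLS], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read/write ground-truth 3D coordinates
#'
#' Columns: `frame_index,timestamp_s,x_cm,y_cm,z_cm`.
#'
#' @param path CSV file path.
#' @return Data frame of 3D points ordered by frame.
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "timestamp_s", "x_cm", "y_cm", "z_cm")
  if (length(setdiff(need, names(df)))) {
    stop("ground-truth CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$frame_index <- as.integer(df$frame_index)
  df[order(df$frame_index), need]
}

#' @rdname read_truth_csv
#' @param points data frame with the ground-truth columns.
#' @export
write_truth_csv <- function(points, path) {
  utils::write.csv(points[, c("frame_index", "timestamp_s",
                              "x_cm", "y_cm", "z_cm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Keep detections at or above a confidence threshold
#'
#' The boundary is inclusive: a detection with confidence exactly equal to the
#' threshold is kept. Row order is preserved and the frame set is unchanged
#' (a frame whose detections are all filtered out becomes an empty frame, not
#' a missing one).
#'
#' @param stream a detection stream (or any detection data frame).
#' @param threshold confidence cutoff in `[0, 1]`.
#' @return The filtered stream.
#' @export
filter_by_confidence <- function(stream, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  out <- stream[stream$confidence >= threshold, , drop = FALSE]
  attr(out, "frame_set") <- attr(stream, "frame_set")
  class(out) <- class(stream)
  out
}

#' Reduce a frame's detections to the single most confident one
#'
#' Ties keep the earliest row (stable file order), matching a single-animal
#' setting where at most one detection per frame is real.
#'
#' @param frame detection rows for one frame.
#' @return A one-row data frame, or `NULL` for an empty frame.
#' @export
select_primary <- function(frame) {
  if (nrow(frame) == 0) return(NULL)
  frame[which.max(frame$confidence), , drop = FALSE]
}

#' Synchronize two camera streams frame-by-frame
#'
#' Pairs the top and side streams on `frame_index`. The output covers the
#' union of the two frame sets; a frame present in only one stream yields a
#' pair whose other side is empty.
#'
#' @param top,side detection streams tagged `"top"` and `"side"`, or lists of
#'   one-frame streams (as returned by [parse_yolo_frame()]).
#' @param dt sampling interval used to cross-check timestamps.
#' @return An object of class `sync_pairs`: a list with `frames` (data frame
#'   of `frame_index`, `timestamp_s`, `n_top`, `n_side`), and the two streams.
#' @export
pair_streams <- function(top, side, dt = 0.1) {
  top <- collect_frames(top, "top")
  side <- collect_frames(side, "side")
  if (nrow(top) && !all(top$camera == "top")) stop("top stream has non-top rows")
  if (nrow(side) && !all(side$camera == "side")) stop("side stream has non-side rows")
  idx <- sort(union(frame_set(top), frame_set(side)))
  frames <- data.frame(frame_index = idx, timestamp_s = idx * dt,
                       n_top = tabulate_frames(top, idx),
                       n_side = tabulate_frames(side, idx))
  check_timestamps(top, dt, "top")
  check_timestamps(side, dt, "side")
  structure(list(frames = frames, top = top, side = side, dt = dt),
            class = "sync_pairs")
}

collect_frames <- function(x, camera) {
  if (is.data.frame(x)) return(x)
  idx <- unlist(lapply(x, frame_set))
  if (anyDuplicated(idx)) {
    stop("duplicate frame_index ", idx[duplicated(idx)][1],
         " in ", camera, " stream")
  }
  new_stream(do.call(rbind, c(list(empty_stream_df()),
                              lapply(x, as.data.frame))),
             frame_set = idx)
}

tabulate_frames <- function(stream, idx) {
  as.integer(table(factor(stream$frame_index, levels = idx)))
}

check_timestamps <- function(stream, dt, label) {
  if (nrow(stream) == 0) return(invisible())
  bad <- abs(stream$timestamp_s - stream$frame_index * dt) > 1e-9
  if (any(bad)) {
    stop(label, " stream timestamp inconsistent with frame_index * dt at frame ",
         stream$frame_index[bad][1])
  }
  invisible()
}

#' @export
print.sync_pairs <- function(x, ...) {
  cat(sprintf("Synchronized pairs: %d frames (%d top / %d side detections)\n",
              nrow(x$frames), nrow(x$top), nrow(x$side)))
  both <- sum(x$frames$n_top > 0 & x$frames$n_side > 0)
  cat(sprintf("  frames detected in both views: %d\n", both))
  invisible(x)
}
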