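box <- function(cx, cy, w, h) c(cx, cy, w, h)

test_that("iou handles identity, disjoint and partial overlap", {
  b <- box(0.5, 0.5, 0.2, 0.1)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(box(0.2, 0.2, 0.1, 0.1), box(0.8, 0.8, 0.1, 0.1)), 0)
  # unit squares overlapping by half: inter 0.5, union 1.5
  expect_equal(iou(box(0.5, 0.5, 1, 1), box(1, 0.5, 1, 1)), 1 / 3)
  expect_equal(iou(box(0.5, 0.5, 0, 0), box(0.5, 0.5, 0, 0)), 0)
})

test_that("iou agrees with an area-arithmetic oracle on random boxes", {
  set.seed(61)
  for (i in 1:200) {
    a <- c(runif(2), runif(2, 0.05, 0.4))
    b <- c(runif(2), runif(2, 0.05, 0.4))
    ax <- c(a[1] - a[3] / 2, a[1] + a[3] / 2); ay <- c(a[2] - a[4] / 2, a[2] + a[4] / 2)
    bx <- c(b[1] - b[3] / 2, b[1] + b[3] / 2); by <- c(b[2] - b[4] / 2, b[2] + b[4] / 2)
    inter <- max(0, min(ax[2], bx[2]) - max(ax[1], bx[1])) *
      max(0, min(ay[2], by[2]) - max(ay[1], by[1]))
    expect_equal(iou(a, b), inter / (a[3] * a[4] + b[3] * b[4] - inter),
                 tolerance = 1e-12)
  }
})

dets_df <- function(cx, cy, w, h, conf) {
  n <- length(cx)
  data.frame(cx = cx, cy = cy, w = rep_len(w, n), h = rep_len(h, n),
             confidence = rep_len(conf, n))
}

test_that("frame matching classifies tp, fp, fn and tn", {
  truth <- dets_df(0.5, 0.5, 0.2, 0.1, 1)[, 1:4]
  hit <- dets_df(0.51, 0.5, 0.2, 0.1, 0.95)
  c1 <- match_frame(hit, truth, iou_thr = 0.5, conf_thr = 0.9)
  expect_equal(c1$tp, 1)
  expect_equal(c1$fp + c1$fn + c1$tn, 0)

  # detection filtered out by confidence leaves the truth unmatched
  c2 <- match_frame(dets_df(0.5, 0.5, 0.2, 0.1, 0.85), truth, 0.5, 0.9)
  expect_equal(c2$fn, 1)
  expect_equal(c2$tp, 0)

  # empty frame with no truth is a true negative
  c3 <- match_frame(dets_df(numeric(), numeric(), numeric(), numeric(),
                            numeric()), truth[0, ], 0.5, 0.9)
  expect_equal(c3$tn, 1)
})

test_that("a spurious reflection detection yields tp=1, fp=1", {
  truth <- dets_df(0.5, 0.5, 0.2, 0.1, 1)[, 1:4]
  dets <- dets_df(c(0.5, 0.9), c(0.5, 0.5), 0.2, 0.1, c(0.95, 0.6))
  got <- match_frame(dets, truth, 0.5, 0)
  expect_equal(got$tp, 1)
  expect_equal(got$fp, 1)
  expect_equal(got$fn, 0)
})

test_that("greedy matching agrees with exhaustive assignment on small frames", {
  set.seed(62)
  for (i in 1:60) {
    nd <- sample(0:3, 1); nt <- sample(0:3, 1)
    dets <- dets_df(runif(nd), runif(nd), 0.25, 0.25, runif(nd, 0.5, 1))
    truth <- dets_df(runif(nt), runif(nt), 0.25, 0.25, 1)[, 1:4, drop = FALSE]
    got <- match_frame(dets, truth, iou_thr = 0.3, conf_thr = 0)
    # oracle: maximum matching over all assignments, counting pairs >= thr
    best <- 0
    if (nd > 0 && nt > 0) {
      m <- outer(seq_len(nd), seq_len(nt),
                 Vectorize(function(a, b) iou(dets[a, ], truth[b, ])))
      k <- min(nd, nt)
      for (ds in utils::combn(nd, k, simplify = FALSE)) {
        perms <- function(v) if (length(v) <= 1) list(v) else
          do.call(c, lapply(seq_along(v), function(j)
            lapply(perms(v[-j]), function(p) c(v[j], p))))
        for (ts in utils::combn(nt, k, simplify = FALSE)) {
          for (pp in perms(ts)) {
            best <- max(best, sum(m[cbind(ds, pp)] >= 0.3))
          }
        }
      }
    }
    expect_equal(got$tp, best)
    expect_equal(got$fp, nd - got$tp)
    expect_equal(got$fn, nt - got$tp)
  }
})

test_that("metrics reproduce the published confusion arithmetic", {
  m1 <- metrics(confusion_counts(tp = 942, fp = 0, tn = 0, fn = 58))
  expect_equal(round(100 * unlist(m1), 1),
               c(accuracy = 94.2, precision = 100, recall = 94.2))
  m2 <- metrics(confusion_counts(tp = 981, fp = 0, tn = 0, fn = 19))
  expect_equal(round(100 * unlist(m2), 1),
               c(accuracy = 98.1, precision = 100, recall = 98.1))
  m3 <- metrics(confusion_counts(tp = 5))
  expect_equal(unlist(m3), c(accuracy = 1, precision = 1, recall = 1))
})

test_that("undefined metrics are NA, and all-zero counts error", {
  m <- metrics(confusion_counts(tn = 4))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_equal(m$accuracy, 1)
  expect_error(metrics(confusion_counts()), "zero")
  expect_error(confusion_counts(tp = -1), "non-negative")
})

test_that("error stats summarize per-frame Euclidean errors", {
  est <- make_traj(rbind(c(1, 1, 1)))
  expect_equal(unlist(error_stats(est, est)[c("max_err_cm", "min_err_cm",
                                              "mean_err_cm")]),
               c(max_err_cm = 0, min_err_cm = 0, mean_err_cm = 0))
  truth <- make_traj(rbind(c(1, 4, 5)))  # offset (0, 3, 4)
  s <- error_stats(est, truth)
  expect_equal(s$max_err_cm, 5)
  expect_equal(s$min_err_cm, 5)
  expect_equal(s$mean_err_cm, 5)
  expect_equal(s$n_detected, 1)
  expect_error(error_stats(make_traj(rbind(c(0, 0, 0)), frame_index = 5),
                           make_traj(rbind(c(0, 0, 0)), frame_index = 9)),
               "no frames")
})

test_that("mean 3D Gaussian offset error matches its expectation within 10%", {
  set.seed(63)
  n <- 10000
  sigma <- 0.3
  base <- data.frame(frame_index = 1:n, x_cm = runif(n, 5, 35),
                     y_cm = runif(n, 1, 7), z_cm = runif(n, 1, 13))
  noisy <- base
  noisy[c("x_cm", "y_cm", "z_cm")] <-
    base[c("x_cm", "y_cm", "z_cm")] + rnorm(3 * n, 0, sigma)
  s <- error_stats(noisy, base)
  expected <- sigma * sqrt(2) * gamma(2) / gamma(3 / 2)  # chi distribution, k=3
  expect_lt(abs(s$mean_err_cm - expected) / expected, 0.10)
  expect_true(s$min_err_cm <= s$mean_err_cm && s$mean_err_cm <= s$max_err_cm)
  # permutation invariance of the alignment
  perm <- sample(n)
  s2 <- error_stats(noisy[perm, ], base)
  expect_equal(s2$mean_err_cm, s$mean_err_cm)
})

test_that("model comparison computes signed percent changes from its inputs", {
  initial <- error_stats_from_summary(1329, 10.892, 0.044, 4.467)
  final <- error_stats_from_summary(3632, 0.284, 0.006, 0.428)
  cmp <- compare_models(initial, final)
  expect_equal(round(cmp$max_err_pct_change, 2), -97.39)
  expect_equal(round(cmp$min_err_pct_change, 2), -86.36)
  # recomputed from the table inputs; the table's own "+173.11%" is off
  expect_equal(round(cmp$coord_pct_change, 2), 173.29)

  same <- compare_models(initial, initial)
  expect_equal(unlist(same), c(coord_pct_change = 0, max_err_pct_change = 0,
                               min_err_pct_change = 0,
                               mean_err_pct_change = 0))
  # near-antisymmetry of the sign for small changes
  a <- error_stats_from_summary(100, 1, 0.1, 0.5)
  b <- error_stats_from_summary(101, 1.01, 0.101, 0.505)
  expect_equal(compare_models(a, b)$max_err_pct_change,
               -compare_models(b, a)$max_err_pct_change, tolerance = 0.05)

  zero <- error_stats_from_summary(10, 1, 0, 0.5)
  expect_true(is.na(compare_models(zero, final)$min_err_pct_change))
})

test_that("evaluation JSON report carries confusion, metrics and comparison", {
  path <- tempfile(fileext = ".json")
  write_evaluation_json(path,
                        counts = confusion_counts(tp = 9, fn = 1),
                        stats = error_stats_from_summary(10, 1, 0.1, 0.5),
                        comparison = compare_models(
                          error_stats_from_summary(10, 1, 0.1, 0.5),
                          error_stats_from_summary(20, 0.5, 0.05, 0.25)))
  rep <- jsonlite::read_json(path)
  expect_equal(rep$confusion$tp, 9)
  expect_equal(rep$metrics$recall, 0.9)
  expect_equal(rep$comparison$coord_pct_change, 100)
  file.remove(path)
})
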