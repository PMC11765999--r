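test_that("interval IOU counts frames inclusively and is symmetric", {
  expect_equal(interval_iou(c(1, 12), c(1, 12)), 1.0)
  expect_equal(interval_iou(c(1, 10), c(11, 20)), 0.0)
  expect_equal(interval_iou(c(1, 12), c(7, 18)), 6 / 18)
  set.seed(3)
  for (k in 1:20) {
    a <- sort(sample(1:50, 2)); b <- sort(sample(1:50, 2))
    expect_equal(interval_iou(a, b), interval_iou(b, a))
    expect_gte(interval_iou(a, b), 0)
    expect_lte(interval_iou(a, b), 1)
  }
})

test_that("the correspondence matrix applies the IOU rule entrywise", {
  truth <- tibble::tibble(eye = "left", start_frame = 1, end_frame = 12)
  pred <- tibble::tibble(eye = "left", start_frame = 7, end_frame = 18)
  R <- build_correspondence_matrix(truth, pred, 0.2)
  expect_equal(unclass(R)[1, 1], 1L, ignore_attr = TRUE)  # IOU 1/3 >= 0.2
  pred2 <- tibble::tibble(eye = "left", start_frame = 30, end_frame = 41)
  expect_equal(sum(build_correspondence_matrix(truth, pred2)), 0)
  R0 <- build_correspondence_matrix(truth[0, ], pred)
  expect_equal(dim(R0), c(0L, 1L))
})

test_that("the worked-example matrix yields the published count chain", {
  R <- worked_example_matrix()
  expect_equal(count_fn(R), 1L)       # row 7 empty
  expect_equal(excess_row(R), 2L)
  expect_equal(excess_col(R), 2L)
  expect_equal(double_counted(R), 1L)
  expect_equal(count_fp(R), 4L)       # 2 + 2 - 1 + empty column 5
  expect_equal(sum(R), 9)
  expect_equal(count_tp(R), 5L)       # 9 - 4
})

test_that("one-to-one matchings have no excess and clean counts", {
  I4 <- diag(1L, 4, 4)
  expect_equal(count_fn(I4), 0L)
  expect_equal(excess_row(I4), 0L)
  expect_equal(excess_col(I4), 0L)
  expect_equal(double_counted(I4), 0L)
  expect_equal(count_fp(I4), 0L)
  expect_equal(count_tp(I4), 4L)
  Z <- matrix(0L, 3, 2)
  expect_equal(count_fn(Z), 3L)
  expect_equal(count_fp(Z), 2L)
})

test_that("the 2x2 example with a shared prediction resolves per the formulas", {
  R <- rbind(c(1L, 1L), c(0L, 1L))
  expect_equal(excess_row(R), 1L)
  expect_equal(excess_col(R), 1L)
  expect_equal(double_counted(R), 1L)
  expect_equal(count_fp(R), 1L)
  expect_equal(count_tp(R), 2L)
})

test_that("excess formulas match brute-force loops on random matrices", {
  set.seed(99)
  for (k in 1:1000) {
    g <- sample(1:8, 1); p <- sample(1:8, 1)
    R <- matrix(rbinom(g * p, 1, runif(1, 0.1, 0.6)), g, p)
    a_ref <- 0L; b_ref <- 0L; c_ref <- 0L
    for (i in seq_len(g)) {
      if (sum(R[i, ]) > 1) a_ref <- a_ref + sum(R[i, ]) - 1L
    }
    for (j in seq_len(p)) {
      if (sum(R[, j]) > 1) b_ref <- b_ref + sum(R[, j]) - 1L
    }
    for (i in seq_len(g)) for (j in seq_len(p)) {
      if (R[i, j] == 1 && sum(R[i, ]) > 1 && sum(R[, j]) > 1) c_ref <- c_ref + 1L
    }
    expect_equal(excess_row(R), a_ref)
    expect_equal(excess_col(R), b_ref)
    expect_equal(double_counted(R), c_ref)
    expect_equal(count_fn(R), sum(rowSums(R) == 0))
    expect_equal(suppressWarnings(count_tp(R)), sum(R) - count_fp(R))
  }
})

test_that("counts are invariant under simultaneous row/column permutations", {
  R <- worked_example_matrix()
  set.seed(5)
  for (k in 1:10) {
    Rp <- R[sample(nrow(R)), sample(ncol(R))]
    expect_equal(detection_counts(Rp), detection_counts(R))
  }
})

test_that("scores reproduce every published total row", {
  rows <- published_rows()
  for (i in seq_len(nrow(rows))) {
    sc <- detection_scores(rows[i, c("tp", "fp", "fn")])
    expect_equal(round(sc$accuracy, 2), rows$accuracy[i], info = rows$method[i])
    expect_equal(round(sc$f1, 2), rows$f1[i], info = rows$method[i])
  }
})

test_that("F1 dominates accuracy whenever errors exist", {
  set.seed(8)
  for (k in 1:20) {
    tp <- sample(0:50, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp + fn == 0) next
    sc <- detection_scores(list(tp = tp, fp = fp, fn = fn))
    if (fp + fn > 0 && tp > 0) expect_gt(sc$f1, sc$accuracy)
  }
  sc <- detection_scores(list(tp = 7, fp = 0, fn = 0))
  expect_equal(sc$accuracy, 100)
  expect_equal(sc$f1, 100)
  expect_error(detection_scores(list(tp = 0, fp = 0, fn = 0)),
               class = "blinkdetect_undefined_score")
})

test_that("frame accuracy is the matching fraction in percent", {
  m <- rep(c(0, 1), 10)
  expect_equal(frame_accuracy(m, m), 100)
  expect_equal(frame_accuracy(m, 1 - m), 0)
  a <- c(rep(1, 90), rep(0, 10)); b <- rep(1, 100)
  expect_equal(frame_accuracy(a, b), 90)
  expect_error(frame_accuracy(1:3, 1:4), class = "blinkdetect_bad_input")
})

test_that("evaluation keeps eyes separate and sums them in the total", {
  truth <- tibble::tibble(eye = c("left", "right"),
                          start_frame = c(10L, 10L), end_frame = c(21L, 21L))
  pred <- tibble::tibble(eye = "left", start_frame = 10L, end_frame = 21L)
  ev <- evaluate_detections(pred, truth)
  td <- tidy(ev)
  expect_equal(td$tp[td$eye == "left"], 1L)
  expect_equal(td$fn[td$eye == "right"], 1L)   # right-eye truth unmatched
  expect_equal(td$fp[td$eye == "right"], 0L)
  tot <- glance(ev)
  expect_equal(tot$tp, 1L)
  expect_equal(tot$fn, 1L)
  expect_equal(tot$accuracy, 50)
})
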