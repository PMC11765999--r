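#' Intersection over union of two frame intervals
#'
#' Frames are counted inclusively on both ends, so `[1, 12]` has 12 frames.
#'
#' @param x,y Length-2 vectors `c(start, end)` (or one-row data frames with
#'   `start_frame`/`end_frame` columns).
#' @return The ratio of shared to combined frames, in `[0, 1]`; symmetric.
#' @export
#' @examples
#' interval_iou(c(1, 12), c(7, 18))  # 6 shared of 18 -> 1/3
interval_iou <- function(x, y) {
  x <- as_interval(x)
  y <- as_interval(y)
  inter <- max(0L, min(x[2], y[2]) - max(x[1], y[1]) + 1L)
  union <- (x[2] - x[1] + 1L) + (y[2] - y[1] + 1L) - inter
  inter / union
}

as_interval <- function(x) {
  if (is.data.frame(x)) x <- c(x$start_frame[1], x$end_frame[1])
  if (length(x) != 2L || x[1] > x[2]) {
    abort("An interval is c(start, end) with start <= end.",
          class = "blinkdetect_bad_input")
  }
  as.numeric(x)
}

#' Build the truth-by-prediction correspondence matrix
#'
#' Entry `R[i, j]` is 1 when ground-truth blink i and predicted blink j
#' overlap with IOU at or above the threshold, else 0. Rows are ground-truth
#' blinks, columns predicted blinks; either side may be empty, giving a
#' 0-row or 0-column matrix.
#'
#' @param truth,pred Data frames with `start_frame` and `end_frame` columns
#'   (one eye at a time), or lists of `c(start, end)` pairs.
#' @param iou_threshold Matching cutoff (default 0.2).
#' @return A binary integer matrix of class `correspondence_matrix`, with the
#'   threshold attached as attribute `iou_threshold`.
#' @export
build_correspondence_matrix <- function(truth, pred, iou_threshold = 0.2) {
  truth <- interval_list(truth)
  pred <- interval_list(pred)
  m <- matrix(0L, nrow = length(truth), ncol = length(pred))
  for (i in seq_along(truth)) {
    for (j in seq_along(pred)) {
      m[i, j] <- as.integer(interval_iou(truth[[i]], pred[[j]]) >= iou_threshold)
    }
  }
  structure(m, iou_threshold = iou_threshold,
            class = c("correspondence_matrix", class(m)))
}

interval_list <- function(x) {
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) c(x$start_frame[i], x$end_frame[i]))
  } else if (is.list(x)) {
    x
  } else {
    abort("Intervals must be a data frame or a list of c(start, end) pairs.",
          class = "blinkdetect_bad_input")
  }
}

#' Event-level counts from a correspondence matrix
#'
#' The detection counts are derived purely from the binary matrix. A false
#' negative is a ground-truth blink matched by no prediction (an all-zero
#' row). False positives combine three sources: extra predictions matched to
#' one truth (`a`, the row excess), predictions that pool several truths
#' (`b`, the column excess) minus entries counted in both (`c`), plus
#' predictions matching nothing (all-zero columns). True positives are the
#' matrix total minus the false positives.
#'
#' @param R A `correspondence_matrix` (any binary matrix works).
#' @return `count_fn`, `count_fp`, `count_tp`, `excess_row`, `excess_col` and
#'   `double_counted` return single integers; `detection_counts` returns a
#'   one-row tibble with `tp`, `fp`, `fn`, `a`, `b`, `c`.
#' @export
#' @examples
#' R <- matrix(0L, 2, 2); diag(R) <- 1L
#' detection_counts(R)
count_fn <- function(R) {
  if (nrow(R) == 0L) return(0L)
  sum(rowSums(R) == 0)
}

#' @rdname count_fn
#' @export
excess_row <- function(R) {
  rs <- rowSums(R)
  as.integer(sum(pmax(rs - 1, 0)))
}

#' @rdname count_fn
#' @export
excess_col <- function(R) {
  cs <- colSums(R)
  as.integer(sum(pmax(cs - 1, 0)))
}

#' @rdname count_fn
#' @export
double_counted <- function(R) {
  if (length(R) == 0L) return(0L)
  rs <- rowSums(R)
  cs <- colSums(R)
  as.integer(sum(R * outer(rs > 1, cs > 1)))
}

#' @rdname count_fn
#' @export
count_fp <- function(R) {
  empty_cols <- if (ncol(R) == 0L) 0L else sum(colSums(R) == 0)
  as.integer(excess_row(R) + excess_col(R) - double_counted(R) + empty_cols)
}

#' @rdname count_fn
#' @export
count_tp <- function(R) {
  tp <- as.integer(sum(R) - count_fp(R))
  if (tp < 0L) {
    warn(sprintf("Correspondence matrix yields negative TP (%d); the count definitions assume matrices arising from real detections.", tp),
         class = "blinkdetect_negative_tp")
  }
  tp
}

#' @rdname count_fn
#' @export
detection_counts <- function(R) {
  tibble(tp = count_tp(R), fp = count_fp(R), fn = count_fn(R),
         a = excess_row(R), b = excess_col(R), c = double_counted(R))
}

#' Blink-level accuracy and F1 from detection counts
#'
#' Accuracy is `100 * TP / (TP + FP + FN)` and F1 is
#' `100 * 2 TP / (2 TP + FP + FN)`; true negatives are undefined for event
#' detection and do not enter either score.
#'
#' @param counts A one-row data frame with `tp`, `fp`, `fn` columns (as from
#'   [detection_counts()]), or a named list/vector with those entries.
#' @return A one-row tibble with `accuracy` and `f1`, both in percent.
#' @export
#' @examples
#' detection_scores(list(tp = 1106, fp = 94, fn = 66))
detection_scores <- function(counts) {
  counts <- as.list(counts)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, fn) < 0)) {
    abort("Counts must be non-negative.", class = "blinkdetect_bad_input")
  }
  if (tp + fp + fn == 0) {
    abort("Scores are undefined when TP + FP + FN = 0.",
          class = "blinkdetect_undefined_score")
  }
  tibble(accuracy = 100 * tp / (tp + fp + fn),
         f1 = 100 * 2 * tp / (2 * tp + fp + fn))
}

#' Frame-level classification accuracy
#'
#' @param pred_mask,truth_mask Equal-length binary (or logical) vectors, one
#'   entry per frame, 1/TRUE marking blink frames.
#' @return Percent of frames whose labels agree.
#' @export
frame_accuracy <- function(pred_mask, truth_mask) {
  if (length(pred_mask) != length(truth_mask)) {
    abort("Masks must have equal length.", class = "blinkdetect_bad_input")
  }
  100 * mean(as.logical(pred_mask) == as.logical(truth_mask))
}

#' Convert blink intervals to a per-frame mask
#'
#' @param intervals Data frame with `start_frame`, `end_frame`.
#' @param n Total number of frames.
#' @return Logical vector of length `n`, TRUE on blink frames.
#' @export
intervals_to_mask <- function(intervals, n) {
  mask <- logical(n)
  for (i in seq_len(nrow(intervals))) {
    mask[intervals$start_frame[i]:min(n, intervals$end_frame[i])] <- TRUE
  }
  mask
}

#' Evaluate predicted blinks against ground truth
#'
#' Matches per eye: for each eye present in either table a correspondence
#' matrix is built at the IOU threshold and the event-level counts and scores
#' derived; a `total` row sums the per-eye counts (eyes are never matched
#' against each other).
#'
#' @param pred,truth Tibbles with columns `eye`, `start_frame`, `end_frame`.
#' @param iou_threshold Matching cutoff (default 0.2).
#' @return An object of class `blink_eval`; use [tidy()] for the per-eye
#'   count table and [glance()] for the one-row total with scores.
#' @export
#' @examples
#' truth <- tibble::tibble(eye = "left", start_frame = c(10, 60), end_frame = c(21, 71))
#' pred <- tibble::tibble(eye = "left", start_frame = c(11, 90), end_frame = c(20, 95))
#' glance(evaluate_detections(pred, truth))
evaluate_detections <- function(pred, truth, iou_threshold = 0.2) {
  check_annotation_frame(pred, "pred")
  check_annotation_frame(truth, "truth")
  eyes <- sort(unique(c(pred$eye, truth$eye)))
  per_eye <- purrr::map_dfr(eyes, function(e) {
    R <- build_correspondence_matrix(truth[truth$eye == e, ],
                                     pred[pred$eye == e, ],
                                     iou_threshold)
    dplyr::mutate(detection_counts(R), eye = e, .before = 1)
  })
  total <- dplyr::summarise(per_eye, eye = "total",
                            dplyr::across(c("tp", "fp", "fn", "a", "b", "c"), sum))
  structure(list(per_eye = per_eye, total = total,
                 iou_threshold = iou_threshold),
            class = "blink_eval")
}

check_annotation_frame <- function(x, what) {
  if (!is.data.frame(x) ||
      !all(c("eye", "start_frame", "end_frame") %in% names(x))) {
    abort(sprintf("`%s` must have columns eye, start_frame, end_frame.", what),
          class = "blinkdetect_bad_input")
  }
  invisible(x)
}

#' @export
print.blink_eval <- function(x, ...) {
  cat(sprintf("<blink_eval> IOU threshold %.2f\n", x$iou_threshold))
  print(tidy(x))
  tot <- glance(x)
  cat(sprintf("total: TP=%d FP=%d FN=%d  accuracy=%.2f%%  F1=%.2f%%\n",
              tot$tp, tot$fp, tot$fn, tot$accuracy, tot$f1))
  invisible(x)
}

#' @export
tidy.blink_eval <- function(x, ...) {
  rows <- dplyr::bind_rows(x$per_eye, x$total)
  scores <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    if (rows$tp[i] + rows$fp[i] + rows$fn[i] == 0) {
      tibble(accuracy = NA_real_, f1 = NA_real_)
    } else {
      detection_scores(rows[i, ])
    }
  })
  dplyr::bind_cols(rows, scores)
}

#' @export
glance.blink_eval <- function(x, ...) {
  dplyr::bind_cols(x$total, detection_scores(x$total))
}

#' @export
autoplot.blink_eval <- function(object, ...) {
  df <- tidy(object)
  df <- tidyr_pivot_counts(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eye, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "blinks", fill = NULL) +
    ggplot2::theme_minimal()
}

# small local reshape to avoid importing tidyr for one call
tidyr_pivot_counts <- function(df) {
  purrr::map_dfr(c("tp", "fp", "fn"), function(k) {
    tibble(eye = df$eye, kind = toupper(k), count = df[[k]])
  })
}
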