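#' Segmentation configuration for blink detection
#'
#' Parameters of the accumulator-to-intervals stage. The accumulator threshold
#' defaults to half the expected blink duration (`threshold_t = ns / 2 = 6`
#' for the default 12-frame window), the morphological structuring element to
#' length 3, and classifier scores are binarized at 0.5 before voting.
#'
#' @param ns Subsequence window length in frames.
#' @param se_length Length of the flat structuring element used for grayscale
#'   closing of the accumulator; must be odd.
#' @param threshold_t Accumulator threshold deciding which watershed segments
#'   contain a blink and which frames belong to it; in `(0, ns]`.
#' @param binarize_cutoff Probability cutoff applied to classifier scores
#'   before they are accumulated as 0/1 votes; in `(0, 1)`.
#' @param soft If `TRUE`, accumulate raw classifier scores instead of binary
#'   votes (extension; off by default, and the accumulator is then no longer
#'   integer-valued).
#'
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(ns = 12, se_length = 3, threshold_t = 6,
                       binarize_cutoff = 0.5, soft = FALSE) {
  if (se_length < 1 || se_length %% 2 == 0) {
    abort("`se_length` must be odd and >= 1.", class = "blinkdetect_bad_param")
  }
  if (threshold_t <= 0 || threshold_t > ns) {
    abort("`threshold_t` must lie in (0, ns].", class = "blinkdetect_bad_param")
  }
  if (binarize_cutoff <= 0 || binarize_cutoff >= 1) {
    abort("`binarize_cutoff` must lie in (0, 1).", class = "blinkdetect_bad_param")
  }
  structure(list(ns = as.integer(ns), se_length = as.integer(se_length),
                 threshold_t = threshold_t, binarize_cutoff = binarize_cutoff,
                 soft = isTRUE(soft)),
            class = "seg_config")
}

#' Build a prediction accumulator from a window classifier
#'
#' Slides the classifier over every dense-overlap window of the sequence,
#' binarizes each score at `cfg$binarize_cutoff` and adds the resulting 0/1
#' vote to every frame the window covers. The accumulator value at frame i is
#' therefore the number of positive windows covering i, an integer in
#' `[0, ns]`.
#'
#' @param seq An [eye_sequence()].
#' @param classifier A window classifier: a function taking a window (a list
#'   with `start` and `data`, as produced by [extract_windows()]) and
#'   returning a blink score in `[0, 1]`. See [oracle_classifier()] and
#'   [as_window_classifier()].
#' @param cfg A [seg_config()].
#'
#' @return An object of class `blink_accumulator`: a list with `values`
#'   (length-N vector) and `ns`.
#' @export
accumulate_predictions <- function(seq, classifier, cfg = seg_config()) {
  stopifnot(inherits(seq, "eye_sequence"))
  n <- n_frames(seq)
  ns <- cfg$ns
  if (n < ns) {
    abort(sprintf("Sequence too short: %d frames but window length is %d.", n, ns),
          class = "blinkdetect_sequence_too_short")
  }
  values <- numeric(n)
  for (s in seq_len(n - ns + 1L)) {
    win <- list(start = s, length = ns,
                data = seq$frames[, , s:(s + ns - 1L), drop = FALSE])
    p <- classifier(win)
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      abort(sprintf("Classifier returned %s for window at frame %d; scores must be a single value in [0, 1].",
                    deparse(p), s),
            class = "blinkdetect_contract_violation")
    }
    vote <- if (cfg$soft) p else as.numeric(p >= cfg$binarize_cutoff)
    idx <- s:(s + ns - 1L)
    values[idx] <- values[idx] + vote
  }
  if (!cfg$soft) values <- as.integer(round(values))
  structure(list(values = values, ns = ns), class = "blink_accumulator")
}

#' @export
print.blink_accumulator <- function(x, ...) {
  cat(sprintf("<blink_accumulator> %d frames, window ns = %d, peak = %g\n",
              length(x$values), x$ns, max(x$values)))
  invisible(x)
}

#' @export
as_tibble.blink_accumulator <- function(x, ...) {
  tibble(frame = seq_along(x$values), value = as.numeric(x$values))
}

# Grayscale dilation/erosion of a 1D signal with a flat centered structuring
# element. Beyond the signal ends dilation pads with the minimum and erosion
# with the maximum, which for truncated windows means simply ignoring the
# padding -- closing then never hallucinates peaks at the edges.
dilate1d <- function(v, se_length) {
  r <- (se_length - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) max(v[max(1L, i - r):min(n, i + r)]), numeric(1))
}

erode1d <- function(v, se_length) {
  r <- (se_length - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) min(v[max(1L, i - r):min(n, i + r)]), numeric(1))
}

#' Grayscale morphological closing of an accumulator
#'
#' Closing (dilation followed by erosion with the same flat structuring
#' element) fills dips narrower than the structuring element, preventing
#' over-segmentation of a single blink into several watershed basins. The
#' operation is extensive (output >= input pointwise) and idempotent.
#'
#' @param acc A `blink_accumulator` (or bare numeric vector).
#' @param se_length Odd structuring-element length (default 3).
#'
#' @return The closed accumulator, same class as the input.
#' @export
morphological_close <- function(acc, se_length = 3) {
  if (se_length < 1 || se_length %% 2 == 0) {
    abort("`se_length` must be odd and >= 1.", class = "blinkdetect_bad_param")
  }
  v <- if (inherits(acc, "blink_accumulator")) acc$values else acc
  closed <- erode1d(dilate1d(v, se_length), se_length)
  if (inherits(acc, "blink_accumulator")) {
    acc$values <- if (is.integer(v)) as.integer(round(closed)) else closed
    acc
  } else {
    closed
  }
}

# Regional maxima plateaus of a 1D signal: maximal runs of constant value
# whose existing neighbors are strictly lower. Returns a matrix with one row
# per plateau (columns: first, last index). A constant signal is one plateau.
regional_maxima <- function(v) {
  n <- length(v)
  runs_end <- c(which(diff(v) != 0), n)
  runs_start <- c(1L, head(runs_end, -1L) + 1L)
  keep <- vapply(seq_along(runs_start), function(j) {
    s <- runs_start[j]; e <- runs_end[j]
    left_ok <- s == 1L || v[s - 1L] < v[s]
    right_ok <- e == n || v[e + 1L] < v[e]
    left_ok && right_ok
  }, logical(1))
  cbind(first = runs_start[keep], last = runs_end[keep])
}

#' Watershed segmentation of an accumulator
#'
#' Splits the frame axis into contiguous basins by applying a 1D watershed to
#' the negative of the (closed) accumulator: one segment per regional maximum
#' of the signal, with segment boundaries at the minima between consecutive
#' maxima. This is what separates blinks occurring in rapid succession, whose
#' accumulator peaks share elevated values. Minimum-plateau boundary frames
#' are assigned to the earlier (left) basin; when a gap holds several equal
#' minima the first one is the cut. Deterministic, processed left to right.
#'
#' @param acc A `blink_accumulator` (ideally after [morphological_close()]) or
#'   bare numeric vector.
#'
#' @return An integer vector of segment labels (1, 2, ...), one per frame;
#'   labels partition `1..N` into contiguous runs.
#' @export
watershed_segment <- function(acc) {
  v <- if (inherits(acc, "blink_accumulator")) acc$values else acc
  n <- length(v)
  peaks <- regional_maxima(v)
  k <- nrow(peaks)
  labels <- integer(n)
  if (k <= 1L) return(rep(1L, n))
  cuts <- integer(k - 1L)  # last frame of each segment but the final one
  for (j in seq_len(k - 1L)) {
    gap <- (peaks[j, "last"] + 1L):(peaks[j + 1L, "first"] - 1L)
    m <- min(v[gap])
    min_idx <- gap[v[gap] == m]
    # first minimal plateau within the gap
    plateau_end <- min_idx[1L]
    while ((plateau_end + 1L) %in% min_idx) plateau_end <- plateau_end + 1L
    cuts[j] <- plateau_end
  }
  bounds <- c(0L, cuts, n)
  for (j in seq_len(k)) {
    labels[(bounds[j] + 1L):bounds[j + 1L]] <- j
  }
  labels
}

#' Extract blink intervals from a segmented accumulator
#'
#' Applies the accumulator threshold per watershed segment: a segment whose
#' peak value reaches `cfg$threshold_t` emits one blink interval, the maximal
#' contiguous run of frames within the segment whose value stays at or above
#' the threshold and which contains the segment's peak (earliest peak on
#' ties). Segments with sub-threshold peaks emit nothing.
#'
#' @param acc The (closed) `blink_accumulator` the labels were derived from,
#'   or a bare numeric vector.
#' @param labels Segment labels from [watershed_segment()].
#' @param cfg A [seg_config()].
#' @param side Which eye the intervals belong to.
#'
#' @return A tibble with columns `eye`, `start_frame`, `end_frame` (1-based,
#'   inclusive), sorted by start and non-overlapping.
#' @export
extract_blinks <- function(acc, labels, cfg = seg_config(),
                           side = c("left", "right")) {
  side <- match.arg(side)
  v <- if (inherits(acc, "blink_accumulator")) acc$values else acc
  if (length(labels) != length(v)) {
    abort("`labels` must have one entry per accumulator frame.",
          class = "blinkdetect_bad_input")
  }
  out <- list()
  for (seg in unique(labels)) {
    idx <- which(labels == seg)
    peak_val <- max(v[idx])
    if (peak_val < cfg$threshold_t) next
    peak_pos <- idx[which.max(v[idx])]  # earliest peak position on ties
    above <- v[idx] >= cfg$threshold_t
    # maximal run of supra-threshold frames (within the segment) holding peak
    pos_in_seg <- match(peak_pos, idx)
    lo <- pos_in_seg
    while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- pos_in_seg
    while (hi < length(idx) && above[hi + 1L]) hi <- hi + 1L
    out[[length(out) + 1L]] <- tibble(eye = side,
                                      start_frame = idx[lo],
                                      end_frame = idx[hi])
  }
  if (length(out) == 0L) {
    return(tibble(eye = character(), start_frame = integer(),
                  end_frame = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_frame)
}

#' Detect blinks in an eye sequence
#'
#' The full inference pipeline for one eye: accumulate binarized window votes
#' over all dense-overlap subsequences, close the accumulator with a short
#' flat structuring element, split it into basins with a 1D watershed on its
#' negative, and threshold each basin into at most one blink interval.
#' Deterministic given fixed classifier weights.
#'
#' @inheritParams accumulate_predictions
#' @param side Eye label for the output intervals; defaults to the
#'   sequence's own side.
#'
#' @return A tibble of blink intervals (`eye`, `start_frame`, `end_frame`),
#'   with the raw and closed accumulators attached as attributes
#'   `accumulator` and `closed`; class `blink_detections`.
#' @export
#' @examples
#' sched <- sample_schedule(300, seed = 7)
#' seq <- render_sequence(sched, scene_config(rng_seed = 7))
#' det <- detect_blinks(seq$sequence, oracle_classifier(seq$truth))
#' det
detect_blinks <- function(seq, classifier, cfg = seg_config(),
                          side = NULL) {
  side <- side %||% seq$side
  acc <- accumulate_predictions(seq, classifier, cfg)
  closed <- morphological_close(acc, cfg$se_length)
  labels <- watershed_segment(closed)
  res <- extract_blinks(closed, labels, cfg, side = side)
  attr(res, "accumulator") <- acc
  attr(res, "closed") <- closed
  attr(res, "config") <- cfg
  class(res) <- c("blink_detections", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
tidy.blink_detections <- function(x, ...) {
  tibble(eye = x$eye, start_frame = x$start_frame, end_frame = x$end_frame)
}

#' Plot a prediction accumulator
#'
#' Line plot of the per-frame vote count, with the segmentation threshold
#' drawn as a dashed rule.
#'
#' @param object A `blink_accumulator`.
#' @param threshold_t Optional threshold to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.blink_accumulator <- function(object, threshold_t = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "accumulated votes") +
    ggplot2::theme_minimal()
  if (!is.null(threshold_t)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_t, linetype = "dashed")
  }
  p
}

#' Plot detected blink intervals over their accumulator
#'
#' @param object A `blink_detections` result from [detect_blinks()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.blink_detections <- function(object, ...) {
  acc <- attr(object, "closed") %||% attr(object, "accumulator")
  cfg <- attr(object, "config")
  p <- autoplot(acc, threshold_t = cfg$threshold_t)
  if (nrow(object) > 0) {
    df <- tidy(object)
    p <- p + ggplot2::geom_rect(
      data = df,
      ggplot2::aes(xmin = .data$start_frame - 0.5, xmax = .data$end_frame + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "magenta",
      inherit.aes = FALSE
    )
  }
  p
}
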