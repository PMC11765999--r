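#' Sample a blink schedule
#'
#' Draws a reproducible sequence of non-overlapping blinks for a synthetic
#' video. Blink durations follow a discretized normal distribution with mean
#' 12 frames and sd 2 (minimum 6), matching a median blink of about 300 ms at
#' 25 fps; the closed core lasts 3 or 4 frames with equal probability. Gaps
#' between blinks are exponential with mean `mean_gap` frames (minimum 1).
#'
#' @param n_frames Total video length in frames.
#' @param mean_gap Mean open-eye gap between consecutive blinks, in frames.
#' @param seed Integer seed; the schedule is a pure function of the seed.
#' @param fps Frames per second (default 25).
#' @param duration_mean,duration_sd,duration_min Parameters of the discretized
#'   normal blink-duration distribution.
#'
#' @return A tibble of class `blink_schedule` with columns `start_frame`,
#'   `duration`, `core_frames`, plus attributes `n_frames` and `fps`. The
#'   blink occupies frames `start_frame .. start_frame + duration - 1`.
#' @export
#' @examples
#' sample_schedule(500, seed = 1)
sample_schedule <- function(n_frames, mean_gap = 60, seed = 1, fps = 25,
                            duration_mean = 12, duration_sd = 2,
                            duration_min = 6) {
  if (n_frames <= 0) {
    abort("`n_frames` must be positive.", class = "blinkdetect_bad_input")
  }
  if (mean_gap < 1) {
    abort("`mean_gap` below 1 frame makes non-overlapping blinks infeasible.",
          class = "blinkdetect_infeasible_density")
  }
  rows <- with_local_seed(seed, {
    out <- list()
    pos <- 1L + max(1L, round(stats::rexp(1, 1 / mean_gap)))
    repeat {
      dur <- sample_duration(1, duration_mean, duration_sd, duration_min)
      if (pos + dur - 1L > n_frames) break
      core <- sample(3:4, 1)
      out[[length(out) + 1L]] <- tibble(start_frame = as.integer(pos),
                                        duration = as.integer(dur),
                                        core_frames = as.integer(core))
      pos <- pos + dur + max(1L, round(stats::rexp(1, 1 / mean_gap)))
    }
    out
  })
  sched <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(start_frame = integer(), duration = integer(),
           core_frames = integer())
  attr(sched, "n_frames") <- as.integer(n_frames)
  attr(sched, "fps") <- fps
  class(sched) <- c("blink_schedule", class(sched))
  sched
}

sample_duration <- function(n, mean = 12, sd = 2, min = 6) {
  pmax(as.integer(min), as.integer(round(rnorm(n, mean, sd))))
}

#' Schedule as ground-truth annotation intervals
#'
#' @param sched A [sample_schedule()] result.
#' @param side Eye label for the annotations.
#' @return A tibble with `eye`, `start_frame`, `end_frame`.
#' @export
schedule_truth <- function(sched, side = "left") {
  tibble(eye = side,
         start_frame = sched$start_frame,
         end_frame = sched$start_frame + sched$duration - 1L)
}

#' Scene configuration for the synthetic eye renderer
#'
#' Describes the simple procedural eye: a bright sclera ellipse holding a
#' dark iris disk on a skin-tone background, with an eyelid that descends and
#' ascends along a piecewise-linear close--hold--open profile during each
#' blink. Additive Gaussian pixel noise and integer frame jitter emulate
#' camera noise and small head movements. No attempt at photorealism is made;
#' the scene only guarantees a monotone mapping from palpebral aperture to
#' appearance.
#'
#' @param width,height Frame size in pixels (the pipeline expects 48 x 48).
#' @param skin,sclera,iris Intensity levels (0--255).
#' @param iris_radius Iris radius in pixels.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param jitter_px Maximum absolute per-frame integer translation.
#' @param min_aperture Residual palpebral aperture during the closed core.
#' @param rng_seed Seed for noise and jitter.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 48, height = 48, skin = 130, sclera = 210,
                         iris = 50, iris_radius = 7, noise_sd = 8,
                         jitter_px = 1, min_aperture = 0.05, rng_seed = 1) {
  lv <- c(skin, sclera, iris)
  if (any(lv < 0 | lv > 255)) {
    abort("Intensity levels must lie in [0, 255].",
          class = "blinkdetect_bad_input")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.", class = "blinkdetect_bad_input")
  }
  structure(list(width = width, height = height, skin = skin, sclera = sclera,
                 iris = iris, iris_radius = iris_radius, noise_sd = noise_sd,
                 jitter_px = jitter_px, min_aperture = min_aperture,
                 rng_seed = rng_seed),
            class = "scene_config")
}

# Per-frame palpebral aperture in [0, 1] for a whole schedule: 1 when open;
# during a blink, linear descent to min_aperture, a hold over the closed
# core, then linear ascent.
aperture_profile <- function(sched, n_frames, min_aperture = 0.05) {
  a <- rep(1, n_frames)
  for (i in seq_len(nrow(sched))) {
    d <- sched$duration[i]
    m <- sched$core_frames[i]
    s <- sched$start_frame[i]
    close_len <- (d - m) %/% 2L
    open_len <- d - m - close_len
    prof <- c(
      if (close_len > 0)
        1 - (1 - min_aperture) * (seq_len(close_len) / (close_len + 1)),
      rep(min_aperture, m),
      if (open_len > 0)
        min_aperture + (1 - min_aperture) * (seq_len(open_len) / (open_len + 1))
    )
    a[s:(s + d - 1L)] <- prof
  }
  a
}

# Render one frame given an aperture and an integer jitter offset.
render_frame <- function(scene, aperture, dx = 0, dy = 0) {
  w <- scene$width; h <- scene$height
  cx <- (w + 1) / 2 + dx
  cy <- (h + 1) / 2 + dy
  rx <- w * 0.38
  ry <- h * 0.21
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  img <- matrix(scene$skin, nrow = h, ncol = w)
  in_eye <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  img[in_eye] <- scene$sclera
  in_iris <- (xs - cx)^2 + (ys - cy)^2 <= scene$iris_radius^2
  img[in_iris & in_eye] <- scene$iris
  # upper eyelid edge sweeps from the sclera top (aperture 1) to its bottom
  lid_edge <- cy - ry + 2 * ry * (1 - aperture)
  covered <- in_eye & (ys < lid_edge)
  img[covered] <- scene$skin
  img
}

#' Render a synthetic eye sequence from a blink schedule
#'
#' Produces the 8-bit 48 x 48 x N stack together with its ground-truth blink
#' annotations. During closed-core frames the palpebral aperture is minimal,
#' so the sclera region's mean intensity is strictly lower than in fully open
#' frames. Rendering is bit-reproducible given the scene seed.
#'
#' @param sched A [sample_schedule()] result.
#' @param scene A [scene_config()].
#' @param side Eye label.
#' @return A list with `sequence` (an [eye_sequence()]) and `truth` (a tibble
#'   `eye`, `start_frame`, `end_frame`).
#' @export
render_sequence <- function(sched, scene = scene_config(), side = "left") {
  n <- attr(sched, "n_frames")
  fps <- attr(sched, "fps") %||% 25
  aperture <- aperture_profile(sched, n, scene$min_aperture)
  frames <- with_local_seed(scene$rng_seed, {
    jit <- if (scene$jitter_px > 0) {
      matrix(sample(-scene$jitter_px:scene$jitter_px, 2L * n, replace = TRUE),
             ncol = 2)
    } else {
      matrix(0L, nrow = n, ncol = 2)
    }
    arr <- array(0, dim = c(scene$height, scene$width, n))
    for (t in seq_len(n)) {
      img <- render_frame(scene, aperture[t], jit[t, 1], jit[t, 2])
      if (scene$noise_sd > 0) {
        img <- img + matrix(rnorm(length(img), 0, scene$noise_sd),
                            nrow = nrow(img))
      }
      arr[, , t] <- pmin(255, pmax(0, round(img)))
    }
    arr
  })
  list(sequence = eye_sequence(frames, side = side, fps = fps),
       truth = schedule_truth(sched, side = side))
}

# Closed-core interval of each truth blink: the centered m frames.
core_intervals <- function(truth, m = 3) {
  starts <- truth$start_frame
  ends <- truth$end_frame
  dur <- ends - starts + 1L
  m <- pmin(m, dur)
  core_start <- starts + (dur - m) %/% 2L
  cbind(core_start, core_start + m - 1L)
}

#' Oracle window classifier from ground truth
#'
#' Returns a window classifier that outputs 1 exactly when the window fully
#' contains the closed core of some annotated blink, else 0. An isolated
#' blink with an `m`-frame core is therefore voted for by `ns - m + 1`
#' windows. The oracle lets the accumulator, watershed and metrics stages be
#' exercised independently of any learned model.
#'
#' @param truth Tibble with `start_frame`, `end_frame` (and optionally
#'   `core_frames`) for one eye; a [sample_schedule()] can be passed through
#'   [schedule_truth()] first.
#' @param ns Window length.
#' @param m Core length used when `truth` lacks a `core_frames` column.
#' @return A classifier function suitable for [accumulate_predictions()].
#' @export
oracle_classifier <- function(truth, ns = 12, m = 3) {
  cores <- if ("core_frames" %in% names(truth) && nrow(truth) > 0) {
    do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      core_intervals(truth[i, ], truth$core_frames[i])
    }))
  } else {
    core_intervals(truth, m)
  }
  function(window) {
    lo <- window$start
    hi <- window$start + dim(window$data)[3] - 1L
    if (nrow(truth) == 0L) return(0)
    hit <- any(cores[, 1] >= lo & cores[, 2] <= hi)
    as.numeric(hit)
  }
}

#' Corrupt a window classifier with seeded label flips
#'
#' Each window's binary vote is flipped independently with probability
#' `flip_prob`; the flip decision is a deterministic function of the seed and
#' the window start, so repeated runs (in any order) agree.
#'
#' @param classifier A window classifier returning scores in `[0, 1]`.
#' @param flip_prob Flip probability, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A classifier function.
#' @export
noisy_oracle <- function(classifier, flip_prob, seed = 1) {
  if (flip_prob < 0 || flip_prob >= 0.5) {
    abort("`flip_prob` must lie in [0, 0.5).", class = "blinkdetect_bad_param")
  }
  function(window) {
    p <- classifier(window)
    if (flip_prob == 0) return(p)
    u <- with_local_seed((seed * 1000003L + window$start) %% .Machine$integer.max,
                         runif(1))
    if (u < flip_prob) 1 - round(p) else p
  }
}

#' Build a labeled training set from annotated sequences
#'
#' Positive windows start at each annotated blink's first frame (one window
#' per blink); negative windows are sampled uniformly among starts whose
#' window shares no frame with any blink, matched 1:1 with the positives.
#' When too few blink-free starts exist the negatives are subsampled with a
#' warning.
#'
#' @param sequences An [eye_sequence()] or list of them.
#' @param truths Matching annotation tibble or list of tibbles.
#' @param ns Window length.
#' @param seed Seed for negative sampling.
#' @return A list of class `labeled_windows` with elements `windows` (list of
#'   48 x 48 x `ns` arrays), `labels` (integer 0/1) and `summary` (a tibble of
#'   class counts).
#' @export
export_training_set <- function(sequences, truths, ns = 12, seed = 1) {
  if (inherits(sequences, "eye_sequence")) sequences <- list(sequences)
  if (is.data.frame(truths)) truths <- list(truths)
  stopifnot(length(sequences) == length(truths))
  windows <- list()
  labels <- integer()
  for (k in seq_along(sequences)) {
    seq_k <- sequences[[k]]
    truth <- truths[[k]]
    n <- n_frames(seq_k)
    pos_starts <- truth$start_frame[truth$start_frame + ns - 1L <= n]
    blink_mask <- intervals_to_mask(truth, n)
    ok_start <- vapply(seq_len(n - ns + 1L), function(s) {
      !any(blink_mask[s:(s + ns - 1L)])
    }, logical(1))
    free_starts <- which(ok_start)
    n_neg <- length(pos_starts)
    if (length(free_starts) < n_neg) {
      warn(sprintf("Only %d blink-free starts available for %d negatives; subsampling.",
                   length(free_starts), n_neg),
           class = "blinkdetect_few_negatives")
      n_neg <- length(free_starts)
    }
    neg_starts <- with_local_seed(seed + k,
                                  sample(free_starts, n_neg, replace = FALSE))
    for (s in pos_starts) {
      windows[[length(windows) + 1L]] <- seq_k$frames[, , s:(s + ns - 1L), drop = FALSE]
      labels <- c(labels, 1L)
    }
    for (s in neg_starts) {
      windows[[length(windows) + 1L]] <- seq_k$frames[, , s:(s + ns - 1L), drop = FALSE]
      labels <- c(labels, 0L)
    }
  }
  structure(list(windows = windows, labels = labels,
                 summary = tibble(class = c("blink", "no_blink"),
                                  n = c(sum(labels == 1L), sum(labels == 0L)))),
            class = "labeled_windows")
}

#' @export
print.labeled_windows <- function(x, ...) {
  cat(sprintf("<labeled_windows> %d windows (%d blink / %d no-blink)\n",
              length(x$windows), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}
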