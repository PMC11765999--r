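#' Construct an eye sequence
#'
#' An `eye_sequence` is a cropped single-eye grayscale video: a 48 x 48 x N
#' intensity stack (8-bit, values 0--255) with a nominal frame rate. Frame
#' indices are 1-based throughout the package and blink intervals are
#' inclusive on both ends.
#'
#' @param frames A numeric 3D array, height x width x N, values in 0--255.
#' @param side Which eye the crop comes from, `"left"` or `"right"`.
#' @param fps Frames per second of the source video (default 25).
#'
#' @return An object of class `eye_sequence`.
#' @export
#' @examples
#' seq <- eye_sequence(array(128, dim = c(48, 48, 20)))
#' n_frames(seq)
eye_sequence <- function(frames, side = c("left", "right"), fps = 25) {
  side <- match.arg(side)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a 3D array (height x width x n_frames).",
          class = "blinkdetect_bad_input")
  }
  if (dim(frames)[3] < 1L) {
    abort("An eye sequence needs at least one frame.",
          class = "blinkdetect_bad_input")
  }
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255) {
    abort("Frame intensities must lie in [0, 255].",
          class = "blinkdetect_bad_input")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort("`fps` must be a positive scalar.", class = "blinkdetect_bad_input")
  }
  structure(list(frames = frames, side = side, fps = fps),
            class = "eye_sequence")
}

#' Number of frames in an eye sequence
#'
#' @param seq An [eye_sequence()].
#' @return Integer frame count N.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "eye_sequence"))
  dim(seq$frames)[3]
}

#' @export
print.eye_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<eye_sequence> %s eye, %d x %d x %d frames @ %g fps (%.1f s)\n",
              x$side, d[1], d[2], d[3], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Extract all dense-overlap subsequence windows
#'
#' Slides a window of `ns` frames over the sequence with step 1 (overlap
#' `ns - 1`), so a sequence of N frames yields `N - ns + 1` windows and every
#' frame is covered by up to `ns` of them. Each window carries its 1-based
#' start index and the contiguous sub-stack it covers.
#'
#' @param seq An [eye_sequence()].
#' @param ns Window length in frames (default 12, about 300 ms at 25 fps).
#'
#' @return A list of windows; each is a list with elements `start`, `length`
#'   and `data` (a height x width x `ns` array).
#' @export
extract_windows <- function(seq, ns = 12) {
  stopifnot(inherits(seq, "eye_sequence"))
  n <- n_frames(seq)
  if (n < ns) {
    abort(sprintf("Sequence too short: %d frames but window length is %d.", n, ns),
          class = "blinkdetect_sequence_too_short")
  }
  lapply(seq_len(n - ns + 1L), function(s) {
    list(start = s, length = ns,
         data = seq$frames[, , s:(s + ns - 1L), drop = FALSE])
  })
}

# Number of length-ns windows covering frame i of an N-frame sequence under
# dense overlap: min(i, N - ns + 1, ns, N - i + 1).
window_coverage <- function(n, ns) {
  i <- seq_len(n)
  pmin(i, n - ns + 1L, ns, n - i + 1L)
}
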