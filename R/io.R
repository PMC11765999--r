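#' Read or write blink annotations
#'
#' Annotations are CSVs with header `eye,start_frame,end_frame`, frames
#' 1-based and inclusive on both ends. Reading validates every row and
#' reports offending line numbers (header = line 1).
#'
#' @param path CSV file path.
#' @param records A data frame with columns `eye`, `start_frame`,
#'   `end_frame`.
#' @return `read_annotations` returns a tibble sorted by eye then start;
#'   `write_annotations` returns `path` invisibly. Round trips are identity.
#' @export
read_annotations <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    eye = readr::col_character(),
    start_frame = readr::col_integer(),
    end_frame = readr::col_integer()
  ), progress = FALSE)
  if (!identical(names(raw), c("eye", "start_frame", "end_frame"))) {
    abort("Annotation CSV must have header eye,start_frame,end_frame.",
          class = "blinkdetect_bad_annotations")
  }
  problems <- character()
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L
    if (is.na(raw$eye[i]) || !raw$eye[i] %in% c("left", "right")) {
      problems <- c(problems, sprintf("line %d: unknown eye label %s",
                                      line, deparse(raw$eye[i])))
    }
    if (is.na(raw$start_frame[i]) || is.na(raw$end_frame[i]) ||
        raw$start_frame[i] < 1 || raw$end_frame[i] < raw$start_frame[i]) {
      problems <- c(problems,
                    sprintf("line %d: invalid interval [%s, %s]", line,
                            raw$start_frame[i], raw$end_frame[i]))
    }
  }
  if (length(problems)) {
    abort(paste0("Malformed annotations in ", path, ":\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "blinkdetect_bad_annotations")
  }
  dplyr::arrange(raw, .data$eye, .data$start_frame)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(records, path) {
  check_annotation_frame(records, "records")
  readr::write_csv(records[, c("eye", "start_frame", "end_frame")], path)
  invisible(path)
}

#' Read a grayscale frame stack
#'
#' Accepts a multi-page TIFF or a directory of PNG frames (lexicographic
#' file order = frame order). Images are converted to 8-bit grayscale
#' (channels averaged) and resized to 48 x 48 by nearest neighbor with a
#' warning when the source size differs.
#'
#' @param path TIFF file or directory of PNGs.
#' @param side Eye label for the resulting sequence.
#' @param fps Frames per second.
#' @return An [eye_sequence()].
#' @export
read_stack <- function(path, side = "left", fps = 25) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) {
      abort(sprintf("No PNG frames found in %s.", path),
            class = "blinkdetect_bad_stack")
    }
    pages <- lapply(files, png::readPNG)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 0L) {
      abort(sprintf("No frames in %s.", path), class = "blinkdetect_bad_stack")
    }
  } else {
    abort(sprintf("Cannot read stack: %s does not exist.", path),
          class = "blinkdetect_bad_stack")
  }
  mats <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) pg <- apply(pg, c(1, 2), mean)
    round(pg * 255)
  })
  d <- dim(mats[[1]])
  if (!all(d == c(48L, 48L))) {
    warn(sprintf("Frames are %d x %d; resizing to 48 x 48 (nearest neighbor).",
                 d[1], d[2]),
         class = "blinkdetect_resized")
    mats <- lapply(mats, resize_nn, 48L, 48L)
  }
  frames <- array(0, dim = c(48L, 48L, length(mats)))
  for (t in seq_along(mats)) frames[, , t] <- mats[[t]]
  eye_sequence(frames, side = side, fps = fps)
}

resize_nn <- function(m, h, w) {
  ri <- pmin(nrow(m), pmax(1L, round(seq(1, nrow(m), length.out = h))))
  ci <- pmin(ncol(m), pmax(1L, round(seq(1, ncol(m), length.out = w))))
  m[ri, ci]
}

#' Write an eye sequence as a multi-page TIFF
#'
#' @param seq An [eye_sequence()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(seq, path) {
  stopifnot(inherits(seq, "eye_sequence"))
  pages <- lapply(seq_len(n_frames(seq)), function(t) {
    seq$frames[, , t] / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Pipeline run configuration
#'
#' The constants of the inference pipeline, bundled for provenance: window
#' length, structuring element, accumulator threshold, binarization cutoff,
#' IOU matching threshold, frame rate and seed. `read_run_config` loads the
#' same structure from a YAML file (missing fields take the defaults).
#'
#' @param ns,se_length,threshold_t,binarize_cutoff See [seg_config()].
#' @param iou_threshold Event-matching IOU cutoff.
#' @param fps Frames per second.
#' @param rng_seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ns = 12, se_length = 3, threshold_t = 6,
                       binarize_cutoff = 0.5, iou_threshold = 0.2,
                       fps = 25, rng_seed = 1) {
  seg <- seg_config(ns, se_length, threshold_t, binarize_cutoff)
  if (iou_threshold <= 0 || iou_threshold > 1) {
    abort("`iou_threshold` must lie in (0, 1].", class = "blinkdetect_bad_param")
  }
  structure(c(unclass(seg)[c("ns", "se_length", "threshold_t",
                             "binarize_cutoff")],
              list(iou_threshold = iou_threshold, fps = fps,
                   rng_seed = as.integer(rng_seed))),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

as_seg_config <- function(rc) {
  seg_config(rc$ns, rc$se_length, rc$threshold_t, rc$binarize_cutoff)
}
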