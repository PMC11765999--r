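# Independent brute-force references used to cross-check the pipeline.

# Naive accumulator: enumerate every window, query the classifier, add the
# binarized vote to each covered frame.
brute_accumulator <- function(seq, classifier, ns = 12, cutoff = 0.5) {
  n <- dim(seq$frames)[3]
  values <- numeric(n)
  for (s in seq_len(n - ns + 1L)) {
    win <- list(start = s, length = ns,
                data = seq$frames[, , s:(s + ns - 1L), drop = FALSE])
    vote <- as.numeric(classifier(win) >= cutoff)
    values[s:(s + ns - 1L)] <- values[s:(s + ns - 1L)] + vote
  }
  values
}

# Closing straight from the definition, with explicit min/max padding.
brute_close <- function(v, se = 3) {
  r <- (se - 1) %/% 2
  pad_lo <- rep(min(v), r); pad_hi <- rep(max(v), r)
  d <- sapply(seq_along(v), function(i) {
    w <- c(pad_lo, v, pad_lo)[i:(i + 2 * r)]
    max(w)
  })
  sapply(seq_along(v), function(i) {
    w <- c(pad_hi, d, pad_hi)[i:(i + 2 * r)]
    min(w)
  })
}

# Split one supra-threshold run at the global minima between its internal
# peaks (recursive divide), mirroring basin splitting through a different
# algorithm than the left-to-right watershed labeling.
split_run <- function(v, lo, hi) {
  seg <- v[lo:hi]
  # plateau-aware regional maxima within the run
  rmax <- local({
    n <- length(seg)
    ends <- c(which(diff(seg) != 0), n)
    starts <- c(1, head(ends, -1) + 1)
    keep <- vapply(seq_along(starts), function(j) {
      s <- starts[j]; e <- ends[j]
      (s == 1 || seg[s - 1] < seg[s]) && (e == n || seg[e + 1] < seg[e])
    }, logical(1))
    cbind(starts[keep], ends[keep])
  })
  if (nrow(rmax) <= 1) return(list(c(lo, hi)))
  gap <- (rmax[1, 2] + 1):(rmax[2, 1] - 1)
  m <- min(seg[gap])
  first_min <- gap[seg[gap] == m][1]
  cut <- first_min
  while ((cut + 1) %in% gap && seg[cut + 1] == m) cut <- cut + 1
  c(list(c(lo, lo + cut - 1)), split_run(v, lo + cut, hi))
}

# Full brute-force detector: naive accumulator, definitional closing,
# supra-threshold runs split at minima between peaks.
brute_detect <- function(seq, classifier, ns = 12, se = 3, threshold = 6,
                         cutoff = 0.5) {
  v <- brute_close(brute_accumulator(seq, classifier, ns, cutoff), se)
  above <- v >= threshold
  if (!any(above)) {
    return(data.frame(start_frame = integer(), end_frame = integer()))
  }
  d <- diff(c(0, above, 0))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  pieces <- list()
  for (k in seq_along(starts)) {
    pieces <- c(pieces, split_run(v, starts[k], ends[k]))
  }
  out <- do.call(rbind, pieces)
  data.frame(start_frame = out[, 1], end_frame = out[, 2])
}

# A classifier voting a fixed value regardless of the window.
constant_classifier <- function(p) function(window) p

# A seeded random binary classifier keyed on the window start.
random_classifier <- function(seed, prob = 0.4) {
  function(window) {
    u <- blinkdetect:::with_local_seed(seed * 7919L + window$start, runif(1))
    as.numeric(u < prob)
  }
}

# Blank sequence helper (static mid-gray frames).
blank_sequence <- function(n, value = 128) {
  eye_sequence(array(value, dim = c(48, 48, n)))
}

# The 8 x 8 correspondence matrix consistent with the worked example: unit
# entries at (1,1),(2,2),(2,3),(3,3),(4,4),(5,4),(6,7),(6,8),(8,6).
worked_example_matrix <- function() {
  R <- matrix(0L, 8, 8)
  idx <- rbind(c(1, 1), c(2, 2), c(2, 3), c(3, 3), c(4, 4), c(5, 4),
               c(6, 7), c(6, 8), c(8, 6))
  R[idx] <- 1L
  R
}

# Published event-count totals and their printed accuracy/F1 (both eyes
# summed), used to pin the score formulas.
published_rows <- function() {
  data.frame(
    method = c("de la Cruz", "Fogelton", "Nousias", "3D CNN",
               "3D autoencoder", "3D ResNet"),
    tp = c(952, 833, 1113, 1056, 1050, 1106),
    fn = c(220, 339, 59, 116, 122, 66),
    fp = c(185, 68, 265, 126, 121, 94),
    accuracy = c(70.15, 67.18, 77.45, 81.36, 81.21, 87.36),
    f1 = c(82.46, 80.37, 87.29, 89.72, 89.63, 93.25)
  )
}

tiny_spec <- function(arch) {
  classifier_spec(arch, latent_units = 32, head_units = c(16, 8),
                  dropout_rate = 0, head_dropout = 0, width = 0.25)
}
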