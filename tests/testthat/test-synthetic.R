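test_that("schedules are reproducible, sorted and non-overlapping", {
  s1 <- sample_schedule(500, mean_gap = 40, seed = 10)
  s2 <- sample_schedule(500, mean_gap = 40, seed = 10)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_gte(nrow(s1), 1)
  ends <- s1$start_frame + s1$duration - 1L
  expect_true(all(ends <= 500))
  if (nrow(s1) > 1) {
    expect_true(all(s1$start_frame[-1] > ends[-nrow(s1)]))
  }
  expect_true(all(s1$core_frames %in% 3:4))
  expect_true(all(s1$core_frames <= s1$duration))
  expect_true(all(s1$duration >= 3))
})

test_that("sampled blink durations have a median near 12 frames", {
  set.seed(123)
  d <- blinkdetect:::sample_duration(10000)
  expect_lte(abs(median(d) - 12), 1)
  expect_true(all(d >= 6))
})

test_that("infeasible blink density is rejected", {
  expect_error(sample_schedule(100, mean_gap = 0.2),
               class = "blinkdetect_infeasible_density")
  expect_error(sample_schedule(0), class = "blinkdetect_bad_input")
})

test_that("rendering is bit-reproducible and anchored to the schedule", {
  sched <- sample_schedule(200, mean_gap = 40, seed = 4)
  r1 <- render_sequence(sched, scene_config(rng_seed = 4))
  r2 <- render_sequence(sched, scene_config(rng_seed = 4))
  expect_identical(r1$sequence$frames, r2$sequence$frames)
  expect_identical(r1$truth$start_frame, sched$start_frame)
  expect_identical(r1$truth$end_frame, sched$start_frame + sched$duration - 1L)
  expect_true(all(r1$sequence$frames >= 0 & r1$sequence$frames <= 255))
})

test_that("a blink-free scene has a stable mean intensity", {
  empty <- tibble::tibble(start_frame = integer(), duration = integer(),
                          core_frames = integer())
  attr(empty, "n_frames") <- 60L
  attr(empty, "fps") <- 25
  rs <- render_sequence(empty, scene_config(rng_seed = 9))
  means <- apply(rs$sequence$frames, 3, mean)
  expect_lt(max(means) - min(means), 3)  # noise + jitter only
})

test_that("closed-core frames darken the sclera region", {
  sched <- tibble::tibble(start_frame = 30L, duration = 12L, core_frames = 4L)
  attr(sched, "n_frames") <- 80L
  attr(sched, "fps") <- 25
  rs <- render_sequence(sched, scene_config(rng_seed = 6, noise_sd = 0,
                                            jitter_px = 0))
  # sclera wings either side of the iris, clear of skin and iris pixels
  sclera_mean <- function(t) mean(rs$sequence$frames[20:28, c(10:16, 33:39), t])
  open_mean <- sclera_mean(5)
  core_frames <- 34:37  # centered 4-frame core of a 12-frame blink at 30
  for (t in core_frames) expect_lt(sclera_mean(t), open_mean - 40)
})

test_that("the oracle votes exactly for windows containing a closed core", {
  truth <- tibble::tibble(eye = "left", start_frame = 40L, end_frame = 51L)
  clf <- oracle_classifier(truth, ns = 12, m = 3)
  seq <- blank_sequence(100)
  votes <- vapply(extract_windows(seq, 12), clf, numeric(1))
  # core = frames 44:46; windows fully containing it start at 35:44
  expect_equal(sum(votes), 12 - 3 + 1)
  expect_equal(which(votes == 1), 35:44)
  expect_equal(clf(list(start = 1, data = seq$frames[, , 1:12])), 0)
})

test_that("noisy oracles are seed-stable and collapse to the oracle at 0", {
  truth <- tibble::tibble(eye = "left", start_frame = 40L, end_frame = 51L)
  base <- oracle_classifier(truth)
  seq <- blank_sequence(100)
  wins <- extract_windows(seq, 12)
  clean <- noisy_oracle(base, 0, seed = 3)
  expect_equal(vapply(wins, clean, numeric(1)), vapply(wins, base, numeric(1)))
  n1 <- noisy_oracle(base, 0.2, seed = 3)
  n2 <- noisy_oracle(base, 0.2, seed = 3)
  expect_equal(vapply(wins, n1, numeric(1)), vapply(wins, n2, numeric(1)))
  expect_error(noisy_oracle(base, 0.6), class = "blinkdetect_bad_param")
})

test_that("mild label noise leaves well-separated blinks detected", {
  sched <- tibble::tibble(start_frame = c(50L, 150L, 250L),
                          duration = c(12L, 12L, 12L),
                          core_frames = c(3L, 3L, 4L))
  attr(sched, "n_frames") <- 350L
  attr(sched, "fps") <- 25
  rs <- render_sequence(sched, scene_config(rng_seed = 8))
  clf <- noisy_oracle(oracle_classifier(rs$truth), 0.05, seed = 21)
  det <- detect_blinks(rs$sequence, clf)
  ev <- glance(evaluate_detections(tidy(det), rs$truth))
  expect_equal(ev$tp, 3)
  expect_lte(ev$fp, 1)
})

test_that("training sets pair start-aligned positives with blink-free negatives", {
  sched <- tibble::tibble(start_frame = c(40L, 100L, 160L),
                          duration = c(12L, 10L, 14L),
                          core_frames = c(3L, 3L, 4L))
  attr(sched, "n_frames") <- 260L
  attr(sched, "fps") <- 25
  rs <- render_sequence(sched, scene_config(rng_seed = 12))
  ts <- export_training_set(rs$sequence, rs$truth, ns = 12, seed = 2)
  expect_equal(sum(ts$labels == 1), 3)
  expect_equal(sum(ts$labels == 0), 3)
  expect_true(all(vapply(ts$windows, function(w) all(dim(w) == c(48, 48, 12)),
                         logical(1))))
  # positives replay the annotated starts
  for (i in which(ts$labels == 1)) {
    s <- rs$truth$start_frame[match(i, which(ts$labels == 1))]
    expect_identical(ts$windows[[i]], rs$sequence$frames[, , s:(s + 11)])
  }
  # negatives share no frame with any blink
  mask <- intervals_to_mask(rs$truth, 260)
  blink_cols <- rs$sequence$frames[, , which(mask)]
  for (i in which(ts$labels == 0)) {
    w <- ts$windows[[i]]
    overlap <- vapply(seq_len(260 - 11), function(s) {
      identical(w, rs$sequence$frames[, , s:(s + 11)]) &&
        any(mask[s:(s + 11)])
    }, logical(1))
    expect_false(any(overlap))
  }
})
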