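test_that("closing fills one-frame dips and preserves isolated spikes", {
  expect_equal(morphological_close(c(5, 5, 0, 5, 5), 3), c(5, 5, 5, 5, 5))
  expect_equal(morphological_close(c(0, 0, 5, 0, 0), 3), c(0, 0, 5, 0, 0))
})

test_that("closing is extensive, idempotent and order-preserving", {
  set.seed(42)
  for (k in 1:20) {
    a <- sample(0:12, 40, replace = TRUE)
    b <- pmin(12, a + sample(0:3, 40, replace = TRUE))
    ca <- morphological_close(a, 3)
    expect_true(all(ca >= a))                                  # extensive
    expect_equal(morphological_close(ca, 3), ca)               # idempotent
    expect_true(all(morphological_close(b, 3) >= ca))          # monotone
    expect_equal(ca, brute_close(a, 3))                        # definition
  }
})

test_that("even structuring elements are rejected", {
  expect_error(morphological_close(c(1, 2, 3), 2),
               class = "blinkdetect_bad_param")
  expect_error(seg_config(se_length = 4), class = "blinkdetect_bad_param")
})

test_that("watershed splits the two-peak example at the internal minimum", {
  labels <- watershed_segment(c(0, 1, 5, 1, 0, 1, 6, 1, 0))
  expect_equal(length(unique(labels)), 2)
  expect_equal(labels, c(1, 1, 1, 1, 1, 2, 2, 2, 2))  # boundary after frame 5
})

test_that("monotone and constant signals give a single segment", {
  expect_equal(watershed_segment(1:10), rep(1L, 10))
  expect_equal(watershed_segment(rep(4, 8)), rep(1L, 8))
})

test_that("watershed labels partition frames with one segment per regional maximum", {
  set.seed(7)
  for (k in 1:25) {
    v <- morphological_close(sample(0:12, 30 + k, replace = TRUE), 3)
    labels <- watershed_segment(v)
    n <- length(v)
    expect_equal(sort(unique(labels)), seq_len(max(labels)))
    expect_true(all(diff(labels) %in% c(0, 1)))          # contiguous, ordered
    expect_length(labels, n)
    expect_equal(max(labels), nrow(blinkdetect:::regional_maxima(v)))
  }
})

test_that("thresholded segments emit the supra-threshold run holding the peak", {
  v <- rep(0, 120)
  v[100:108] <- c(6, 7, 9, 12, 12, 10, 8, 7, 6)
  labels <- watershed_segment(v)
  out <- extract_blinks(v, labels, seg_config(threshold_t = 6), side = "left")
  expect_equal(nrow(out), 1)
  expect_equal(out$start_frame, 100)
  expect_equal(out$end_frame, 108)

  low <- rep(0, 40); low[18:22] <- c(2, 3, 4, 3, 2)
  out2 <- extract_blinks(low, watershed_segment(low),
                         seg_config(threshold_t = 6), side = "left")
  expect_equal(nrow(out2), 0)
})

test_that("two supra-threshold segments give two ordered intervals", {
  v <- rep(0, 60)
  v[10:15] <- c(6, 8, 10, 10, 8, 6)
  v[30:34] <- c(7, 9, 11, 9, 7)
  out <- extract_blinks(v, watershed_segment(v), seg_config(), side = "right")
  expect_equal(nrow(out), 2)
  expect_equal(out$start_frame, c(10, 30))
  expect_equal(out$end_frame, c(15, 34))
  expect_true(all(out$eye == "right"))
})
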