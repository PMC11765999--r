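test_that("all three builders emit probabilities in [0, 1] and batch cleanly", {
  set.seed(1)
  wins <- lapply(1:3, function(i) array(runif(48 * 48 * 12, 0, 255),
                                        dim = c(48, 48, 12)))
  for (arch in c("cnn3d", "ae3d", "resnet3d")) {
    m <- suppressMessages(switch(arch,
      cnn3d = build_simple_cnn3d(tiny_spec("cnn3d"), seed = 2),
      ae3d = build_autoencoder3d(tiny_spec("ae3d"), seed = 2),
      resnet3d = build_resnet3d(tiny_spec("resnet3d"), seed = 2)))
    p1 <- predict(m, wins[[1]])
    expect_length(p1, 1)
    expect_true(p1 >= 0 && p1 <= 1)
    pk <- predict(m, wins)
    expect_length(pk, 3)
    expect_true(all(pk >= 0 & pk <= 1))
    expect_identical(predict(m, wins), pk)  # deterministic inference
  }
})

test_that("the autoencoder feature-map chain matches the reference geometry", {
  spec <- classifier_spec("ae3d")
  m <- suppressMessages(build_autoencoder3d(spec, seed = 1))
  g <- m$geoms
  expect_equal(g$g1$out_dims, c(24L, 24L, 6L, 16L))
  expect_equal(g$g2$out_dims, c(12L, 12L, 3L, 32L))
  expect_equal(g$g3$out_dims, c(12L, 12L, 3L, 32L))
  expect_equal(g$g4$out_dims, c(6L, 6L, 3L, 32L))
  expect_equal(spec$latent_units, 2048L)
  # the simple CNN shares the encoder geometry exactly
  mc <- suppressMessages(build_simple_cnn3d(classifier_spec("cnn3d"), seed = 1))
  expect_equal(mc$geoms[c("g1", "g2", "g3", "g4")],
               g[c("g1", "g2", "g3", "g4")])
  # live forward pass produces those shapes and a clipped reconstruction
  x <- array(runif(48 * 48 * 12, 0, 255), dim = c(48, 48, 12))
  fwd <- blinkdetect:::model_forward(m, x)
  expect_length(fwd$enc$b1$out, prod(c(24, 24, 6, 16)))
  expect_length(fwd$enc$b2$out, prod(c(12, 12, 3, 32)))
  expect_length(fwd$enc$b4$out, prod(c(6, 6, 3, 32)))
  expect_length(fwd$enc$lat, 2048)
  rec <- predict(m, x, type = "recon")
  expect_equal(dim(rec), dim(x))
  expect_true(all(rec >= 0 & rec <= 255))
})

test_that("residual blocks preserve shape and the parameter count is compact", {
  m <- suppressMessages(build_resnet3d(classifier_spec("resnet3d"), seed = 3))
  x <- array(runif(48 * 48 * 12, 0, 255), dim = c(48, 48, 12))
  fwd <- blinkdetect:::model_forward(m, x)
  body_len <- prod(m$geoms$proj$out_dims)
  for (b in 1:4) expect_length(fwd$blocks[[b]]$out, body_len)
  expect_lt(n_params(m), 1e6)
  expect_gt(n_params(m), 1e4)
})

test_that("cross-entropy matches its closed forms and a brute-force loop", {
  eps <- 1e-7
  expect_lt(bce_loss(c(eps, 1 - eps), c(0, 1)), 1e-6)
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  p <- c(0.9, 0.2, 0.6); t <- c(1, 0, 1)
  manual <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(bce_loss(p, t), manual, tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), class = "blinkdetect_bad_input")
})

test_that("reconstruction loss is the grand voxel mean of squared error", {
  a <- array(runif(48 * 48 * 12, 0, 255), dim = c(48, 48, 12))
  expect_equal(reconstruction_loss(a, a), 0)
  expect_equal(reconstruction_loss(a, a + 3), 9, tolerance = 1e-10)
  b <- array(runif(48 * 48 * 12, 0, 255), dim = c(48, 48, 12))
  brute <- 0
  for (i in seq_along(a)) brute <- brute + (a[i] - b[i])^2
  expect_equal(reconstruction_loss(a, b), brute / length(a), tolerance = 1e-10)
})

test_that("the composite loss is the stated weighted sum", {
  expect_equal(total_loss(1.0, 2.0), 1.1, tolerance = 1e-12)
  expect_equal(total_loss(0, 0), 0)
  expect_equal(total_loss(3, 100, weights = c(1, 0)), 3)
  expect_error(classifier_spec("ae3d", loss_weights = c(0.5, 0.2)),
               class = "blinkdetect_bad_param")
})

test_that("analytic gradients agree with central differences", {
  grad_probe <- function(m, n_probe = 6, h = 1e-5) {
    set.seed(9)
    x <- array(runif(48 * 48 * 12, 0, 255), dim = c(48, 48, 12))
    fwd <- blinkdetect:::model_forward(m, x)
    grads <- blinkdetect:::model_backward(m, fwd, 1)
    loss_at <- function(mm) {
      blinkdetect:::model_loss(mm, blinkdetect:::model_forward(mm, x), 1)
    }
    # probe weight matrices; bias probes sit on ReLU kinks too often for
    # finite differences to be meaningful
    wnames <- grep("_W$", names(m$params), value = TRUE)
    errs <- numeric()
    set.seed(31)
    for (nm in sample(wnames, min(n_probe, length(wnames)))) {
      k <- sample(length(m$params[[nm]]), 1)
      mp <- m; mp$params[[nm]][k] <- mp$params[[nm]][k] + h
      mm2 <- m; mm2$params[[nm]][k] <- mm2$params[[nm]][k] - h
      num <- (loss_at(mp) - loss_at(mm2)) / (2 * h)
      errs <- c(errs, abs(num - grads[[nm]][k]) /
                  max(1e-6, abs(num) + abs(grads[[nm]][k])))
    }
    errs
  }
  m_cnn <- suppressMessages(build_simple_cnn3d(tiny_spec("cnn3d"), seed = 4))
  expect_lt(max(grad_probe(m_cnn)), 1e-5)
  m_res <- suppressMessages(build_resnet3d(tiny_spec("resnet3d"), seed = 4))
  expect_lt(median(grad_probe(m_res, n_probe = 8)), 1e-4)
  m_ae <- suppressMessages(build_autoencoder3d(tiny_spec("ae3d"), seed = 4))
  expect_lt(median(grad_probe(m_ae, n_probe = 8)), 1e-4)
})

test_that("builders are reproducible given a seed", {
  m1 <- suppressMessages(build_simple_cnn3d(tiny_spec("cnn3d"), seed = 7))
  m2 <- suppressMessages(build_simple_cnn3d(tiny_spec("cnn3d"), seed = 7))
  expect_identical(m1$params, m2$params)
  m3 <- suppressMessages(build_simple_cnn3d(tiny_spec("cnn3d"), seed = 8))
  expect_false(identical(m3$params, m1$params))
})
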