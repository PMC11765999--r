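#' Specification of a 3D subsequence classifier
#'
#' Describes one of the three blink classifier architectures and its
#' hyperparameters. All three consume a 48 x 48 x `ns` grayscale window and
#' emit a blink probability in `[0, 1]`:
#'
#' * `cnn3d` -- a simple 3D CNN: a four-block convolutional encoder, a
#'   fully-connected latent layer, and a classifier head of repeated
#'   fully-connected + ReLU + dropout blocks.
#' * `ae3d` -- a 3D convolutional autoencoder sharing that encoder and head;
#'   a three-block transposed-convolution decoder with skip connections from
#'   encoder blocks 1, 2 and 4 reconstructs the input, capped by a clipped
#'   ReLU with ceiling 255 so reconstructions stay valid 8-bit intensities.
#' * `resnet3d` -- a compact 3D residual network: a convolutional stem and
#'   one stack of four residual blocks at 64 channels (bottleneck form), with
#'   global average pooling and a binary head.
#'
#' @param architecture One of `"cnn3d"`, `"ae3d"`, `"resnet3d"`.
#' @param ns Temporal window length (frames); the autoencoder geometry
#'   requires the default 12.
#' @param latent_units Width of the fully-connected latent layer.
#' @param dropout_rate Dropout rate inside the convolutional encoder.
#' @param head_units Sizes of the fully-connected classifier-head blocks.
#' @param head_dropout Dropout rate in the classifier head.
#' @param loss_weights Two weights `(w_cls, w_rec)` for the composite
#'   autoencoder loss; must sum to 1. The default (0.9, 0.1) favors the
#'   classification term: with equal weights the reconstruction converges
#'   first and the classifier underfits.
#' @param width Channel-width multiplier (1 = the reference architecture);
#'   fractional values give miniature models for quick experiments.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(architecture = c("cnn3d", "ae3d", "resnet3d"),
                            ns = 12, latent_units = 2048, dropout_rate = 0.1,
                            head_units = c(256, 64), head_dropout = 0.3,
                            loss_weights = c(0.9, 0.1), width = 1) {
  architecture <- match.arg(architecture)
  if (latent_units <= 0) {
    abort("`latent_units` must be positive.", class = "blinkdetect_bad_param")
  }
  if (abs(sum(loss_weights) - 1) > 1e-8) {
    abort("`loss_weights` must sum to 1.", class = "blinkdetect_bad_param")
  }
  structure(list(architecture = architecture, ns = as.integer(ns),
                 latent_units = as.integer(latent_units),
                 dropout_rate = dropout_rate,
                 head_units = as.integer(head_units),
                 head_dropout = head_dropout,
                 loss_weights = loss_weights, width = width),
            class = "classifier_spec")
}

scale_ch <- function(base, width) pmax(1L, as.integer(round(base * width)))

encoder_geoms <- function(ns, width) {
  ch <- scale_ch(c(16L, 32L, 32L, 32L), width)
  g1 <- conv_geom(c(48L, 48L, ns, 1L), ch[1], stride = c(2L, 2L, 2L))
  g2 <- conv_geom(g1$out_dims, ch[2], stride = c(2L, 2L, 2L))
  g3 <- conv_geom(g2$out_dims, ch[3], stride = c(1L, 1L, 1L))
  g4 <- conv_geom(g3$out_dims, ch[4], stride = c(2L, 2L, 1L))
  list(g1 = g1, g2 = g2, g3 = g3, g4 = g4, ch = ch)
}

new_blink_model <- function(arch, spec, geoms, params) {
  structure(list(arch = arch, spec = spec, geoms = geoms, params = params),
            class = "blink_model")
}

#' Build the simple 3D CNN blink classifier
#'
#' Four convolutional encoder blocks (identical to the autoencoder's
#' encoder), a fully-connected latent layer, and the fully-connected
#' classifier head. Output is a single blink probability.
#'
#' @param spec A [classifier_spec()] with matching `architecture`.
#' @param seed Seed fixing the random weight initialization.
#' @return A `blink_model`; use [predict()] or [as_window_classifier()].
#' @export
build_simple_cnn3d <- function(spec = classifier_spec("cnn3d"), seed = 1) {
  stopifnot(spec$architecture == "cnn3d")
  g <- encoder_geoms(spec$ns, spec$width)
  params <- with_local_seed(seed, {
    p <- c(prefix("conv1", conv_init(g$g1)), prefix("conv2", conv_init(g$g2)),
           prefix("conv3", conv_init(g$g3)), prefix("conv4", conv_init(g$g4)),
           prefix("latent", dense_init(prod(g$g4$out_dims), spec$latent_units)),
           head_init(spec))
    p
  })
  m <- new_blink_model("cnn3d", spec, g, params)
  inform(sprintf("simple 3D CNN built: %s learnable parameters",
                 format(n_params(m), big.mark = ",")))
  m
}

#' Build the 3D convolutional autoencoder classifier
#'
#' Shares the simple CNN's encoder and classifier head; adds a
#' fully-connected expansion from the latent space and three transposed-
#' convolution decoder blocks with skip connections concatenating the
#' outputs of encoder blocks 4, 2 and 1 onto the matching decoder inputs. A
#' final convolution with a clipped ReLU (ceiling 255) emits the
#' reconstruction. Feature-map chain:
#' `48x48x12x1 -> 24x24x6x16 -> 12x12x3x32 -> 12x12x3x32 -> 6x6x3x32 ->`
#' latent 2048.
#'
#' @inheritParams build_simple_cnn3d
#' @return A `blink_model` whose forward pass yields both a blink
#'   probability and a reconstruction (see [predict.blink_model()]).
#' @export
build_autoencoder3d <- function(spec = classifier_spec("ae3d"), seed = 1) {
  stopifnot(spec$architecture == "ae3d")
  g <- encoder_geoms(spec$ns, spec$width)
  dch <- scale_ch(c(32L, 32L, 16L), spec$width)
  sp4 <- g$g4$out_dims[1:3]; sp2 <- g$g2$out_dims[1:3]
  sp1 <- g$g1$out_dims[1:3]; sp0 <- g$g1$in_dims[1:3]
  g$t1 <- tconv_geom(sp2, dch[1], sp4, 2L * g$ch[4], stride = c(2L, 2L, 1L))
  g$t2 <- tconv_geom(sp1, dch[2], sp2, dch[1] + g$ch[2], stride = c(2L, 2L, 2L))
  g$t3 <- tconv_geom(sp0, dch[3], sp1, dch[2] + g$ch[1], stride = c(2L, 2L, 2L))
  g$gout <- conv_geom(c(sp0, dch[3]), 1L, stride = c(1L, 1L, 1L))
  g$dch <- dch
  params <- with_local_seed(seed, {
    c(prefix("conv1", conv_init(g$g1)), prefix("conv2", conv_init(g$g2)),
      prefix("conv3", conv_init(g$g3)), prefix("conv4", conv_init(g$g4)),
      prefix("latent", dense_init(prod(g$g4$out_dims), spec$latent_units)),
      head_init(spec),
      prefix("dec_fc", dense_init(spec$latent_units, prod(g$g4$out_dims))),
      prefix("t1", tconv_init(g$t1)), prefix("t2", tconv_init(g$t2)),
      prefix("t3", tconv_init(g$t3)), prefix("out", conv_init(g$gout)))
  })
  m <- new_blink_model("ae3d", spec, g, params)
  inform(sprintf("3D autoencoder built: %s learnable parameters",
                 format(n_params(m), big.mark = ",")))
  m
}

#' Build the compact 3D residual network classifier
#'
#' A convolutional stem followed by one stack of four residual blocks whose
#' convolutions carry 64 filters (bottleneck form with identity shortcuts),
#' global average pooling and a 2-way softmax head. The learnable parameter
#' count is reported at build time.
#'
#' @inheritParams build_simple_cnn3d
#' @return A `blink_model`.
#' @export
build_resnet3d <- function(spec = classifier_spec("resnet3d"), seed = 1) {
  stopifnot(spec$architecture == "resnet3d")
  cs <- scale_ch(32L, spec$width)
  cb <- scale_ch(64L, spec$width)
  cm <- scale_ch(32L, spec$width)
  g <- list()
  g$stem <- conv_geom(c(48L, 48L, spec$ns, 1L), cs, stride = c(2L, 2L, 2L))
  g$proj <- conv_geom(g$stem$out_dims, cb, k = c(1L, 1L, 1L))
  body_dims <- g$proj$out_dims
  for (b in 1:4) {
    g[[paste0("b", b, "a")]] <- conv_geom(body_dims, cm, k = c(1L, 1L, 1L))
    g[[paste0("b", b, "b")]] <- conv_geom(c(body_dims[1:3], cm), cm,
                                          k = c(3L, 3L, 3L))
    g[[paste0("b", b, "c")]] <- conv_geom(c(body_dims[1:3], cm), cb,
                                          k = c(1L, 1L, 1L))
  }
  g$cb <- cb
  params <- with_local_seed(seed, {
    p <- c(prefix("stem", conv_init(g$stem)), prefix("proj", conv_init(g$proj)))
    for (b in 1:4) {
      p <- c(p,
             prefix(paste0("b", b, "a"), conv_init(g[[paste0("b", b, "a")]])),
             prefix(paste0("b", b, "b"), conv_init(g[[paste0("b", b, "b")]])),
             prefix(paste0("b", b, "c"), conv_init(g[[paste0("b", b, "c")]])))
    }
    c(p, prefix("fc", dense_init(cb, 2L)))
  })
  m <- new_blink_model("resnet3d", spec, g, params)
  inform(sprintf("3D ResNet built: %s learnable parameters",
                 format(n_params(m), big.mark = ",")))
  m
}

prefix <- function(nm, lst) stats::setNames(lst, paste0(nm, "_", names(lst)))

head_init <- function(spec) {
  sizes <- c(spec$latent_units, spec$head_units, 2L)
  out <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    out <- c(out, prefix(paste0("head", i), dense_init(sizes[i], sizes[i + 1])))
  }
  out
}

#' Number of learnable parameters
#'
#' @param model A `blink_model`.
#' @return Integer count over all weights and biases.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.blink_model <- function(x, ...) {
  cat(sprintf("<blink_model> %s (ns = %d, width = %g): %s parameters\n",
              x$arch, x$spec$ns, x$spec$width,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

enc_block_fwd <- function(x, p, g, nm, rate, train) {
  cv <- conv_fwd(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]], g)
  r <- relu_fwd(cv$y)
  dp <- dropout_fwd(r, rate, train)
  list(out = dp$y, cols = cv$cols, pre = cv$y, mask = dp$mask)
}

enc_block_bwd <- function(dout, cache, p, g, nm) {
  dr <- dropout_bwd(dout, cache$mask)
  dy <- relu_bwd(dr, cache$pre)
  cb <- conv_bwd(dy, cache$cols, p[[paste0(nm, "_W")]], g)
  grads <- stats::setNames(list(cb$dW, cb$db),
                           paste0(nm, c("_W", "_b")))
  list(grads = grads, dx = cb$dx)
}

encoder_fwd <- function(model, xn, train) {
  p <- model$params; g <- model$geoms
  rate <- model$spec$dropout_rate
  b1 <- enc_block_fwd(xn, p, g$g1, "conv1", rate, train)
  b2 <- enc_block_fwd(b1$out, p, g$g2, "conv2", rate, train)
  b3 <- enc_block_fwd(b2$out, p, g$g3, "conv3", rate, train)
  b4 <- enc_block_fwd(b3$out, p, g$g4, "conv4", rate, train)
  lat_pre <- dense_fwd(b4$out, p$latent_W, p$latent_b)
  lat <- relu_fwd(lat_pre)
  list(lat = lat, lat_pre = lat_pre, b1 = b1, b2 = b2, b3 = b3, b4 = b4)
}

encoder_bwd <- function(model, cache, dlat, dskip = NULL, lazy = FALSE) {
  p <- model$params; g <- model$geoms
  dlat_pre <- relu_bwd(dlat, cache$lat_pre)
  dl <- dense_bwd(dlat_pre, cache$b4$out, p$latent_W, lazy = lazy)
  grads <- list(latent_W = dl$dW, latent_b = dl$db)
  d4 <- dl$dx
  if (!is.null(dskip$o4)) d4 <- d4 + dskip$o4
  s4 <- enc_block_bwd(d4, cache$b4, p, g$g4, "conv4")
  s3 <- enc_block_bwd(s4$dx, cache$b3, p, g$g3, "conv3")
  d2 <- s3$dx
  if (!is.null(dskip$o2)) d2 <- d2 + dskip$o2
  s2 <- enc_block_bwd(d2, cache$b2, p, g$g2, "conv2")
  d1 <- s2$dx
  if (!is.null(dskip$o1)) d1 <- d1 + dskip$o1
  s1 <- enc_block_bwd(d1, cache$b1, p, g$g1, "conv1")
  c(grads, s4$grads, s3$grads, s2$grads, s1$grads)
}

head_fwd <- function(model, lat, train) {
  p <- model$params
  rate <- model$spec$head_dropout
  n_blocks <- length(model$spec$head_units)
  x <- lat
  cache <- list(inputs = list(), pre = list(), masks = list())
  for (i in seq_len(n_blocks)) {
    nm <- paste0("head", i)
    cache$inputs[[i]] <- x
    y <- dense_fwd(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    cache$pre[[i]] <- y
    r <- relu_fwd(y)
    dp <- dropout_fwd(r, rate, train)
    cache$masks[i] <- list(dp$mask)
    x <- dp$y
  }
  nm <- paste0("head", n_blocks + 1L)
  cache$inputs[[n_blocks + 1L]] <- x
  logits <- dense_fwd(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
  probs <- softmax2(logits)
  list(prob = probs[2], probs = probs, cache = cache)
}

head_bwd <- function(model, hf, label, lazy = FALSE) {
  p <- model$params
  n_blocks <- length(model$spec$head_units)
  onehot <- c(1 - label, label)
  dlogits <- hf$probs - onehot
  grads <- list()
  nm <- paste0("head", n_blocks + 1L)
  dl <- dense_bwd(dlogits, hf$cache$inputs[[n_blocks + 1L]], p[[paste0(nm, "_W")]])
  grads[[paste0(nm, "_W")]] <- dl$dW
  grads[[paste0(nm, "_b")]] <- dl$db
  dx <- dl$dx
  for (i in rev(seq_len(n_blocks))) {
    nm <- paste0("head", i)
    dr <- dropout_bwd(dx, hf$cache$masks[[i]])
    dy <- relu_bwd(dr, hf$cache$pre[[i]])
    dl <- dense_bwd(dy, hf$cache$inputs[[i]], p[[paste0(nm, "_W")]], lazy = lazy)
    grads[[paste0(nm, "_W")]] <- dl$dW
    grads[[paste0(nm, "_b")]] <- dl$db
    dx <- dl$dx
  }
  list(grads = grads, dlat = dx)
}

decoder_fwd <- function(model, enc, train) {
  p <- model$params; g <- model$geoms
  fc <- dense_fwd(enc$lat, p$dec_fc_W, p$dec_fc_b)
  fcr <- relu_fwd(fc)
  z1 <- c(fcr, enc$b4$out)
  t1 <- tconv_fwd(z1, p$t1_W, p$t1_b, g$t1)
  a1 <- relu_fwd(t1$y)
  z2 <- c(a1, enc$b2$out)
  t2 <- tconv_fwd(z2, p$t2_W, p$t2_b, g$t2)
  a2 <- relu_fwd(t2$y)
  z3 <- c(a2, enc$b1$out)
  t3 <- tconv_fwd(z3, p$t3_W, p$t3_b, g$t3)
  a3 <- relu_fwd(t3$y)
  out <- conv_fwd(a3, p$out_W, p$out_b, g$gout)
  recon <- pmin(255, pmax(0, out$y))  # clipped ReLU, ceiling 255
  list(recon = recon, out_pre = out$y, out_cols = out$cols,
       fc_pre = fc, fcr = fcr, t1 = t1, a1_pre = t1$y, t2 = t2,
       a2_pre = t2$y, t3 = t3, a3_pre = t3$y)
}

decoder_bwd <- function(model, dec, drecon) {
  p <- model$params; g <- model$geoms
  dout <- drecon * (dec$out_pre > 0 & dec$out_pre < 255)
  cb <- conv_bwd(dout, dec$out_cols, p$out_W, g$gout)
  grads <- list(out_W = cb$dW, out_b = cb$db)
  da3 <- relu_bwd(cb$dx, dec$a3_pre)
  t3b <- tconv_bwd(da3, dec$t3$zmat, p$t3_W, g$t3)
  grads$t3_W <- t3b$dW; grads$t3_b <- t3b$db
  n_a2 <- prod(g$t2$in_dims[1:3]) * g$dch[2]
  da2 <- relu_bwd(t3b$dz[seq_len(n_a2)], dec$a2_pre)
  dskip_o1 <- t3b$dz[-seq_len(n_a2)]
  t2b <- tconv_bwd(da2, dec$t2$zmat, p$t2_W, g$t2)
  grads$t2_W <- t2b$dW; grads$t2_b <- t2b$db
  n_a1 <- prod(g$t1$in_dims[1:3]) * g$dch[1]
  da1 <- relu_bwd(t2b$dz[seq_len(n_a1)], dec$a1_pre)
  dskip_o2 <- t2b$dz[-seq_len(n_a1)]
  t1b <- tconv_bwd(da1, dec$t1$zmat, p$t1_W, g$t1)
  grads$t1_W <- t1b$dW; grads$t1_b <- t1b$db
  n_fc <- length(dec$fcr)
  dfcr <- t1b$dz[seq_len(n_fc)]
  dskip_o4 <- t1b$dz[-seq_len(n_fc)]
  dfc <- relu_bwd(dfcr, dec$fc_pre)
  # dec_fc input is the latent; its weight grads and dlat contribution
  list(grads = grads, dfc = dfc,
       dskip = list(o1 = dskip_o1, o2 = dskip_o2, o4 = dskip_o4))
}

res_block_fwd <- function(x, p, g, b) {
  na <- paste0("b", b, "a"); nb <- paste0("b", b, "b"); nc <- paste0("b", b, "c")
  ca <- conv_fwd(x, p[[paste0(na, "_W")]], p[[paste0(na, "_b")]], g[[na]])
  ra <- relu_fwd(ca$y)
  cbv <- conv_fwd(ra, p[[paste0(nb, "_W")]], p[[paste0(nb, "_b")]], g[[nb]])
  rb <- relu_fwd(cbv$y)
  cc <- conv_fwd(rb, p[[paste0(nc, "_W")]], p[[paste0(nc, "_b")]], g[[nc]])
  pre <- x + cc$y
  out <- relu_fwd(pre)
  list(out = out, pre = pre, ca = ca, ra_pre = ca$y, cbv = cbv,
       rb_pre = cbv$y, cc = cc, x = x)
}

res_block_bwd <- function(dout, cache, p, g, b) {
  na <- paste0("b", b, "a"); nb <- paste0("b", b, "b"); nc <- paste0("b", b, "c")
  dpre <- relu_bwd(dout, cache$pre)
  cbc <- conv_bwd(dpre, cache$cc$cols, p[[paste0(nc, "_W")]], g[[nc]])
  drb <- relu_bwd(cbc$dx, cache$rb_pre)
  cbb <- conv_bwd(drb, cache$cbv$cols, p[[paste0(nb, "_W")]], g[[nb]])
  dra <- relu_bwd(cbb$dx, cache$ra_pre)
  cba <- conv_bwd(dra, cache$ca$cols, p[[paste0(na, "_W")]], g[[na]])
  grads <- stats::setNames(list(cba$dW, cba$db, cbb$dW, cbb$db, cbc$dW, cbc$db),
                           c(paste0(na, c("_W", "_b")),
                             paste0(nb, c("_W", "_b")),
                             paste0(nc, c("_W", "_b"))))
  list(grads = grads, dx = cba$dx + dpre)  # identity shortcut
}

model_forward <- function(model, x, train = FALSE) {
  xn <- as.vector(x) / 255
  if (model$arch %in% c("cnn3d", "ae3d")) {
    enc <- encoder_fwd(model, xn, train)
    hf <- head_fwd(model, enc$lat, train)
    dec <- if (model$arch == "ae3d") decoder_fwd(model, enc, train) else NULL
    list(prob = hf$prob, enc = enc, hf = hf, dec = dec, x_raw = as.vector(x))
  } else {
    p <- model$params; g <- model$geoms
    stem <- conv_fwd(xn, p$stem_W, p$stem_b, g$stem)
    rs <- relu_fwd(stem$y)
    proj <- conv_fwd(rs, p$proj_W, p$proj_b, g$proj)
    rp <- relu_fwd(proj$y)
    blocks <- list()
    h <- rp
    for (b in 1:4) {
      blocks[[b]] <- res_block_fwd(h, p, g, b)
      h <- blocks[[b]]$out
    }
    npos <- prod(g$proj$out_dims[1:3])
    feat <- colMeans(matrix(h, nrow = npos))
    logits <- dense_fwd(feat, p$fc_W, p$fc_b)
    probs <- softmax2(logits)
    list(prob = probs[2], probs = probs, stem = stem, rs_pre = stem$y,
         proj = proj, rp_pre = proj$y, blocks = blocks, feat = feat,
         npos = npos)
  }
}

model_backward <- function(model, fwd, label, lazy = FALSE) {
  if (model$arch == "cnn3d") {
    hb <- head_bwd(model, fwd$hf, label, lazy = lazy)
    c(hb$grads, encoder_bwd(model, fwd$enc, hb$dlat, lazy = lazy))
  } else if (model$arch == "ae3d") {
    w <- model$spec$loss_weights
    hb <- head_bwd(model, fwd$hf, label, lazy = lazy)
    grads <- grad_scale(hb$grads, w[1])
    nvox <- length(fwd$x_raw)
    drecon <- w[2] * 2 * (fwd$dec$recon - fwd$x_raw) / nvox
    db <- decoder_bwd(model, fwd$dec, drecon)
    grads <- c(grads, db$grads)
    dl <- dense_bwd(db$dfc, fwd$enc$lat, model$params$dec_fc_W, lazy = lazy)
    grads$dec_fc_W <- dl$dW
    grads$dec_fc_b <- dl$db
    dlat <- w[1] * hb$dlat + dl$dx
    c(grads, encoder_bwd(model, fwd$enc, dlat, dskip = db$dskip, lazy = lazy))
  } else {
    p <- model$params; g <- model$geoms
    onehot <- c(1 - label, label)
    dlogits <- fwd$probs - onehot
    dl <- dense_bwd(dlogits, fwd$feat, p$fc_W)
    grads <- list(fc_W = dl$dW, fc_b = dl$db)
    dh <- rep(dl$dx, each = fwd$npos) / fwd$npos
    for (b in 4:1) {
      rb <- res_block_bwd(dh, fwd$blocks[[b]], p, g, b)
      grads <- c(grads, rb$grads)
      dh <- rb$dx
    }
    drp <- relu_bwd(dh, fwd$rp_pre)
    cbp <- conv_bwd(drp, fwd$proj$cols, p$proj_W, g$proj)
    grads$proj_W <- cbp$dW; grads$proj_b <- cbp$db
    drs <- relu_bwd(cbp$dx, fwd$rs_pre)
    cbs <- conv_bwd(drs, fwd$stem$cols, p$stem_W, g$stem)
    grads$stem_W <- cbs$dW; grads$stem_b <- cbs$db
    grads
  }
}

# Per-sample training loss: Eq-style BCE for classification, plus the
# weighted reconstruction MSE for the autoencoder.
model_loss <- function(model, fwd, label) {
  cls <- bce_loss(fwd$prob, label)
  if (model$arch == "ae3d") {
    rec <- mean((fwd$dec$recon - fwd$x_raw)^2)
    total_loss(cls, rec, model$spec$loss_weights)
  } else {
    cls
  }
}

# ---- prediction ------------------------------------------------------------

#' Predict blink probabilities
#'
#' Runs the classifier forward (dropout disabled) on one or more windows.
#'
#' @param object A `blink_model` or `blink_fit`.
#' @param newdata A single 48 x 48 x ns array, a window (list with `data`),
#'   a list of either, or a `labeled_windows` set.
#' @param type `"prob"` for blink probabilities, `"recon"` for the
#'   autoencoder's reconstruction (single window only).
#' @param ... Ignored.
#' @return Numeric vector of probabilities, or a reconstruction array.
#' @export
predict.blink_model <- function(object, newdata, type = c("prob", "recon"), ...) {
  type <- match.arg(type)
  if (type == "recon") {
    stopifnot(object$arch == "ae3d")
    x <- extract_window_data(newdata)[[1]]
    fwd <- model_forward(object, x, train = FALSE)
    return(array(fwd$dec$recon, dim = dim(x)))
  }
  xs <- extract_window_data(newdata)
  vapply(xs, function(x) model_forward(object, x, train = FALSE)$prob,
         numeric(1))
}

extract_window_data <- function(newdata) {
  if (inherits(newdata, "labeled_windows")) return(newdata$windows)
  if (is.array(newdata)) return(list(newdata))
  if (is.list(newdata) && !is.null(newdata$data)) return(list(newdata$data))
  if (is.list(newdata)) {
    return(lapply(newdata, function(w) if (is.list(w)) w$data else w))
  }
  abort("Cannot interpret `newdata` as windows.", class = "blinkdetect_bad_input")
}

#' Wrap a model as a window classifier
#'
#' Adapts a trained (or freshly built) model to the window-classifier
#' contract used by [accumulate_predictions()] and [detect_blinks()].
#'
#' @param model A `blink_model` or `blink_fit`.
#' @return A function mapping a window to a blink probability in `[0, 1]`.
#' @export
as_window_classifier <- function(model) {
  if (inherits(model, "blink_fit")) model <- model$model
  stopifnot(inherits(model, "blink_model"))
  function(window) model_forward(model, window$data, train = FALSE)$prob
}

# ---- losses ----------------------------------------------------------------

#' Binary cross-entropy over window predictions
#'
#' Mean of `-(t log p + (1 - t) log(1 - p))`; probabilities are clamped away
#' from 0 and 1 by `eps`.
#'
#' @param probs Predicted blink probabilities.
#' @param labels Binary ground-truth labels (same length).
#' @param eps Clamping constant.
#' @return Scalar loss.
#' @export
bce_loss <- function(probs, labels, eps = 1e-7) {
  if (length(probs) != length(labels)) {
    abort("`probs` and `labels` must have equal length.",
          class = "blinkdetect_bad_input")
  }
  p <- pmin(1 - eps, pmax(eps, probs))
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Mean squared reconstruction error
#'
#' Grand mean of squared voxel differences over all windows.
#'
#' @param inputs,reconstructions Arrays (or lists of arrays) of equal shape.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(inputs, reconstructions) {
  if (is.array(inputs)) inputs <- list(inputs)
  if (is.array(reconstructions)) reconstructions <- list(reconstructions)
  if (length(inputs) != length(reconstructions)) {
    abort("Input and reconstruction counts differ.",
          class = "blinkdetect_bad_input")
  }
  sq <- purrr::map2_dbl(inputs, reconstructions, function(a, b) {
    if (!identical(dim(a), dim(b))) {
      abort("Input and reconstruction shapes differ.",
            class = "blinkdetect_bad_input")
    }
    mean((a - b)^2)
  })
  mean(sq)
}

#' Composite autoencoder loss
#'
#' Weighted sum `w_cls * l_cls + w_rec * l_rec` with default weights
#' (0.9, 0.1) favoring the classification term.
#'
#' @param l_cls Classification (cross-entropy) loss.
#' @param l_rec Reconstruction loss.
#' @param weights Length-2 weights summing to 1.
#' @return Scalar loss.
#' @export
total_loss <- function(l_cls, l_rec, weights = c(0.9, 0.1)) {
  if (!is.finite(l_cls) || !is.finite(l_rec)) {
    abort("Losses must be finite.", class = "blinkdetect_bad_input")
  }
  weights[1] * l_cls + weights[2] * l_rec
}
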