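# Minimal 3D convolutional network engine.
#
# Volumes are numeric vectors in column-major (H, W, D, C) order. Convolution
# is implemented as im2col (src/conv3d.cpp) followed by a GEMM, with 'same'
# zero padding of floor(k/2) per side; transposed convolution is the exact
# adjoint of the corresponding strided convolution, so output geometry is
# fixed by construction. All parameters live in a flat named list, which
# keeps the Adam update generic.

conv_geom <- function(in_dims, out_ch, k = c(5L, 5L, 5L), stride = c(1L, 1L, 1L)) {
  k <- as.integer(k); stride <- as.integer(stride)
  pad <- k %/% 2L
  out_sp <- (in_dims[1:3] + 2L * pad - k) %/% stride + 1L
  list(k = k, stride = stride, pad = pad,
       in_dims = as.integer(in_dims), out_dims = as.integer(c(out_sp, out_ch)))
}

conv_init <- function(g) {
  fan_in <- prod(g$k) * g$in_dims[4]
  list(W = matrix(rnorm(fan_in * g$out_dims[4], 0, sqrt(2 / fan_in)),
                  nrow = fan_in),
       b = numeric(g$out_dims[4]))
}

conv_fwd <- function(x, W, b, g) {
  cols <- .vol2col(x, g$in_dims, g$k, g$stride, g$pad)
  y <- cols %*% W
  y <- sweep(y, 2, b, "+")
  list(y = as.vector(y), cols = cols)
}

conv_bwd <- function(dy_vec, cols, W, g) {
  npos <- prod(g$out_dims[1:3])
  dy <- matrix(dy_vec, nrow = npos)
  list(dW = crossprod(cols, dy),
       db = colSums(dy),
       dx = .col2vol(dy %*% t(W), g$in_dims, g$k, g$stride, g$pad))
}

# Transposed convolution: g is the geometry of the *down* convolution from
# the big output volume to the small input volume. Input has g$out_dims
# channels replaced by in_ch; weights are (prod(k) * big_ch) x in_ch.
tconv_geom <- function(big_sp, big_ch, small_sp, in_ch, k = c(5L, 5L, 5L),
                       stride = c(1L, 1L, 1L)) {
  g <- conv_geom(c(big_sp, big_ch), out_ch = in_ch, k = k, stride = stride)
  stopifnot(all(g$out_dims[1:3] == small_sp))
  g$in_ch <- as.integer(in_ch)
  g
}

tconv_init <- function(g) {
  fan_in <- prod(g$k) * g$in_ch  # per output element of the big volume
  nr <- prod(g$k) * g$in_dims[4]
  list(W = matrix(rnorm(nr * g$in_ch, 0, sqrt(2 / fan_in)), nrow = nr),
       b = numeric(g$in_dims[4]))
}

tconv_fwd <- function(z, W, b, g) {
  npos <- prod(g$out_dims[1:3])
  zmat <- matrix(z, nrow = npos)
  y <- .col2vol(zmat %*% t(W), g$in_dims, g$k, g$stride, g$pad)
  big_sp <- prod(g$in_dims[1:3])
  y <- y + rep(b, each = big_sp)
  list(y = y, zmat = zmat)
}

tconv_bwd <- function(dy_vec, zmat, W, g) {
  dcols <- .vol2col(dy_vec, g$in_dims, g$k, g$stride, g$pad)
  big_sp <- prod(g$in_dims[1:3])
  list(dW = crossprod(dcols, zmat),
       db = colSums(matrix(dy_vec, nrow = big_sp)),
       dz = as.vector(dcols %*% W))
}

dense_init <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), nrow = n_in),
       b = numeric(n_out))
}

dense_fwd <- function(x, W, b) as.vector(crossprod(W, x)) + b

# For large dense layers the weight gradient outer(x, dy) dominates memory
# traffic; when `lazy` the factors are kept and the batch total is formed by
# a single GEMM in materialize_grads().
dense_bwd <- function(dy, x, W, lazy = FALSE) {
  dW <- if (lazy && length(x) * length(dy) > 65536) {
    new_lazy_outer(x, dy)
  } else {
    outer(x, dy)
  }
  list(dW = dW, db = dy, dx = as.vector(W %*% dy))
}

new_lazy_outer <- function(x, dy) {
  structure(list(xs = list(x), dys = list(dy)), class = "lazy_outer")
}

materialize_grads <- function(grads) {
  lapply(grads, function(g) {
    if (inherits(g, "lazy_outer")) {
      crossprod(do.call(rbind, g$xs), do.call(rbind, g$dys))
    } else {
      g
    }
  })
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, y) dy * (y > 0)

# Inverted dropout; draws from the current RNG stream (training controls it).
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

softmax2 <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

# Adam with bias correction, operating on flat named parameter lists.
adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

grad_accumulate <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) {
    if (inherits(g[[nm]], "lazy_outer")) {
      total[[nm]]$xs <- c(total[[nm]]$xs, g[[nm]]$xs)
      total[[nm]]$dys <- c(total[[nm]]$dys, g[[nm]]$dys)
    } else {
      total[[nm]] <- total[[nm]] + g[[nm]]
    }
  }
  total
}

grad_scale <- function(grads, f) {
  lapply(grads, function(g) {
    if (inherits(g, "lazy_outer")) {
      g$dys <- lapply(g$dys, function(d) d * f)
      g
    } else {
      g * f
    }
  })
}
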