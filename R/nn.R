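# Minimal dense/convolutional layer library with analytic gradients.
#
# Feature maps are H x W x C arrays (spatial-first); most layers also keep a
# flattened HW x C matrix view, exploiting R's column-major layout so that a
# 3x3 convolution is nine shifted BLAS matrix products. All kernels are 3x3
# with zero padding and stride 1; that is the only spatial receptive field
# the architecture needs.

## y[h, w, ] = x[h + di, w + dj, ], zero outside the frame.
shift2d <- function(x, di, dj) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  y <- array(0, d)
  hs <- max(1L, 1L - di):min(H, H - di)
  ws <- max(1L, 1L - dj):min(W, W - dj)
  y[hs, ws, ] <- x[hs + di, ws + dj, , drop = FALSE]
  y
}

## 3x3 cross-correlation, zero-padded, stride 1.
## x: H x W x Cin; W_: 3 x 3 x Cin x Cout; b: length Cout.
conv2d_fwd <- function(x, W_, b) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; Cin <- d[3L]
  Cout <- dim(W_)[4L]
  hw <- H * Wd
  y <- matrix(b, hw, Cout, byrow = TRUE)
  shifts <- vector("list", 9L)
  n <- 0L
  for (dj in -1:1) for (di in -1:1) {
    n <- n + 1L
    sh <- matrix(shift2d(x, di, dj), hw, Cin)
    shifts[[n]] <- sh
    y <- y + sh %*% matrix(W_[di + 2L, dj + 2L, , ], Cin, Cout)
  }
  list(y = array(y, c(H, Wd, Cout)), shifts = shifts, dim_in = d)
}

conv2d_bwd <- function(cache, W_, dy, need_dx = TRUE) {
  d <- cache$dim_in
  H <- d[1L]; Wd <- d[2L]; Cin <- d[3L]
  Cout <- dim(W_)[4L]
  hw <- H * Wd
  dyarr <- array(dy, c(H, Wd, Cout))
  dymat <- matrix(dy, hw, Cout)
  dW <- array(0, dim(W_))
  dx <- if (need_dx) matrix(0, hw, Cin) else NULL
  n <- 0L
  for (dj in -1:1) for (di in -1:1) {
    n <- n + 1L
    dW[di + 2L, dj + 2L, , ] <- crossprod(cache$shifts[[n]], dymat)
    if (need_dx) {
      dx <- dx + matrix(shift2d(dyarr, -di, -dj), hw, Cout) %*%
        t(matrix(W_[di + 2L, dj + 2L, , ], Cin, Cout))
    }
  }
  list(dW = dW, db = colSums(dymat),
       dx = if (need_dx) array(dx, d) else NULL)
}

## Depthwise 3x3 convolution: one 3x3 kernel per channel (k: 3 x 3 x C).
dwconv_fwd <- function(x, k) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  hw <- H * Wd
  y <- matrix(0, hw, C)
  shifts <- vector("list", 9L)
  n <- 0L
  for (dj in -1:1) for (di in -1:1) {
    n <- n + 1L
    sh <- matrix(shift2d(x, di, dj), hw, C)
    shifts[[n]] <- sh
    y <- y + sh * rep(k[di + 2L, dj + 2L, ], each = hw)
  }
  list(y = array(y, d), shifts = shifts, dim_in = d)
}

dwconv_bwd <- function(cache, k, dy, need_dx = TRUE) {
  d <- cache$dim_in
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  hw <- H * Wd
  dyarr <- array(dy, d)
  dymat <- matrix(dy, hw, C)
  dk <- array(0, dim(k))
  dx <- if (need_dx) matrix(0, hw, C) else NULL
  n <- 0L
  for (dj in -1:1) for (di in -1:1) {
    n <- n + 1L
    dk[di + 2L, dj + 2L, ] <- colSums(cache$shifts[[n]] * dymat)
    if (need_dx) {
      dx <- dx + matrix(shift2d(dyarr, -di, -dj), hw, C) *
        rep(k[di + 2L, dj + 2L, ], each = hw)
    }
  }
  list(dk = dk, dx = if (need_dx) array(dx, d) else NULL)
}

## 1-D zero-padded cross-correlation over the channel axis (no bias); used
## by the efficient-channel-attention block. s: length C; w: odd length.
conv1d_fwd <- function(s, w) {
  C <- length(s)
  r <- (length(w) - 1L) / 2L
  S <- vapply(-r:r, function(m) {
    v <- numeric(C)
    src <- seq_len(C) + m
    ok <- src >= 1L & src <= C
    v[ok] <- s[src[ok]]
    v
  }, numeric(C))
  list(y = drop(S %*% w), S = matrix(S, C, length(w)))
}

conv1d_bwd <- function(cache, w, dy) {
  dw <- drop(crossprod(cache$S, dy))
  ds <- conv1d_fwd(dy, rev(w))$y
  list(dw = dw, ds = ds)
}

## 2x2 average pooling (H, W must be even).
avgpool2_fwd <- function(x) {
  d <- dim(x)
  x1 <- x[seq(1L, d[1L], 2L), , , drop = FALSE] +
        x[seq(2L, d[1L], 2L), , , drop = FALSE]
  (x1[, seq(1L, d[2L], 2L), , drop = FALSE] +
   x1[, seq(2L, d[2L], 2L), , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy) {
  d <- dim(dy)
  up <- dy[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
           drop = FALSE] / 4
  up
}

## Nearest-neighbour 2x upsampling.
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  x1 <- dy[seq(1L, d[1L], 2L), , , drop = FALSE] +
        dy[seq(2L, d[1L], 2L), , , drop = FALSE]
  x1[, seq(1L, d[2L], 2L), , drop = FALSE] +
    x1[, seq(2L, d[2L], 2L), , drop = FALSE]
}

## Glorot-style initialisers (draws from the current RNG stream).
init_conv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin + cout))
  array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
}

init_dense <- function(cin, cout) {
  sd <- sqrt(2 / (cin + cout))
  matrix(stats::rnorm(cin * cout, sd = sd), cin, cout)
}

## Adam optimiser over a named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

## Decoupled weight decay is applied to multiplicative weights only
## (biases and the pooling exponent are exempt via the `decay` name set).
## `decay` names get decoupled weight decay (biases and the pooling
## exponent are exempt); `input_layers` get the extra `input_decay` rate —
## these are the layers reading the gated bands, where stronger shrinkage
## converts band usefulness into sustained gate pressure.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8,
                      trainable = names(params), weight_decay = 0,
                      decay = character(0), input_decay = 0,
                      input_layers = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    step <- lr * mhat / (sqrt(vhat) + eps)
    wd <- 0
    if (nm %in% decay) wd <- weight_decay
    if (nm %in% input_layers) wd <- wd + input_decay
    if (wd > 0) step <- step + lr * wd * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

## Elementwise sum of two named gradient lists (missing entries treated 0).
grad_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)
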