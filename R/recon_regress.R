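# Public wrappers around the network branches, operating on band-first
# cubes (the package convention); the internal engine is spatial-first.

cube_values <- function(x) {
  if (inherits(x, "hyper_cube")) x$values
  else if (inherits(x, "compact_representation")) x$values
  else x
}

to_internal <- function(v) aperm(v, c(2, 3, 1))     # (C,H,W) -> (H,W,C)
to_bandfirst <- function(v) aperm(v, c(3, 1, 2))    # (H,W,C) -> (C,H,W)

#' Spatial attention mask
#'
#' Band-wise mean and max maps are concatenated, filtered by a trainable
#' 3x3 convolution, and squashed through a logistic, yielding a mask in
#' `(0, 1)` over the spatial grid.
#'
#' @param cube [hyper_cube()] or band-first array.
#' @param model an [hsi_model()].
#' @return H x W matrix in `(0, 1)`.
#' @export
spatial_attention <- function(cube, model) {
  v <- cube_values(cube)
  x <- to_internal(v)
  d <- dim(x)
  hw <- d[1] * d[2]
  xmat <- matrix(x, hw, d[3])
  pooled <- array(c(rowMeans(xmat),
                    xmat[cbind(seq_len(hw),
                               max.col(xmat, ties.method = "first"))]),
                  c(d[1], d[2], 2L))
  csp <- conv2d_fwd(pad1_replicate(pooled), model$params$att_sp_W,
                    model$params$att_sp_b)
  matrix(sigmoid(as.vector(csp$y[1L + seq_len(d[1]), 1L + seq_len(d[2]), ])),
         d[1], d[2])
}

#' Spectral (band-importance) attention
#'
#' The per-band spatial mean vector is passed through a small MLP with a
#' logistic output, giving one importance score per band. The output
#' depends on the cube only through the pooled band means.
#'
#' @inheritParams spatial_attention
#' @return length-C importance vector in `(0, 1)`.
#' @export
spectral_attention <- function(cube, model) {
  v <- cube_values(cube)
  C <- dim(v)[1]
  s <- rowMeans(matrix(v, C))
  P <- model$params
  h1 <- relu(drop(s %*% P$att_W1) + P$att_b1)
  sigmoid(drop(h1 %*% P$att_W2) + P$att_b2)
}

## Vector-Jacobian product of spectral_attention with respect to the cube;
## used to validate the analytic gradients against finite differences.
spectral_attention_vjp <- function(cube, model, da) {
  v <- cube_values(cube)
  C <- dim(v)[1]
  hw <- prod(dim(v)[2:3])
  s <- rowMeans(matrix(v, C))
  P <- model$params
  h1pre <- drop(s %*% P$att_W1) + P$att_b1
  h1 <- relu(h1pre)
  a <- sigmoid(drop(h1 %*% P$att_W2) + P$att_b2)
  dapre <- da * a * (1 - a)
  dh1 <- drop(P$att_W2 %*% dapre) * (h1pre > 0)
  ds <- drop(P$att_W1 %*% dh1)
  array(rep(ds / hw, hw), dim(v))
}

#' Reconstruct the full-band cube from a compact representation
#'
#' Runs the two-level encoder-decoder (with skip connection and logistic
#' output) on a gated or masked cube, returning a full C-band cube in
#' `[0, 1]`. Odd spatial sizes are padded internally and cropped back.
#'
#' @param model an [hsi_model()].
#' @param x_k compact representation, [hyper_cube()] or band-first array.
#' @return [hyper_cube()] with the reconstructed values.
#' @export
reconstruct <- function(model, x_k) {
  x <- to_internal(cube_values(x_k))
  P <- model$params
  pe <- pad_even_fwd(x)
  e1 <- relu(conv2d_fwd(pe$y, P$rec_e1_W, P$rec_e1_b)$y)
  e2 <- relu(conv2d_fwd(avgpool2_fwd(e1), P$rec_e2_W, P$rec_e2_b)$y)
  u1 <- upsample2_fwd(e2)
  cat1 <- array(c(u1, e1), c(dim(u1)[1], dim(u1)[2],
                             dim(u1)[3] + dim(e1)[3]))
  d1 <- relu(conv2d_fwd(cat1, P$rec_d1_W, P$rec_d1_b)$y)
  xh <- sigmoid(conv2d_fwd(d1, P$rec_o_W, P$rec_o_b)$y)
  d <- dim(x)
  hyper_cube(to_bandfirst(xh[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]),
             provenance = "normalized")
}

#' Reconstruction loss (mean squared error)
#'
#' @param xhat reconstructed cube or array.
#' @param x ground-truth cube or array of the same shape.
#' @return scalar mean squared error over all voxels.
#' @export
rec_loss <- function(xhat, x) {
  a <- cube_values(xhat); b <- cube_values(x)
  if (!all(dim(a) == dim(b))) stopf("shape mismatch")
  mean((a - b)^2)
}

#' Predict SSC from a compact representation
#'
#' Depthwise separable filtering, efficient channel attention, generalized
#' mean pooling and an affine head produce one scalar prediction in
#' degrees Brix.
#'
#' @inheritParams reconstruct
#' @return scalar predicted SSC.
#' @export
predict_ssc <- function(model, x_k) {
  x <- to_internal(cube_values(x_k))
  P <- model$params
  d <- dim(x)
  hw <- d[1] * d[2]
  t1 <- matrix(dwconv_fwd(x, P$reg_dw_k)$y, hw, d[3])
  t2 <- relu(t1 %*% P$reg_pw_W + rep(P$reg_pw_b, each = hw))
  z <- sigmoid(conv1d_fwd(colMeans(t2), P$reg_eca_w)$y)
  t3 <- t2 * rep(z, each = hw)
  v <- gem_fwd(t3, 1 + exp(as.numeric(P$reg_gem_p)))$v
  as.numeric(v %*% P$reg_head_W) + as.numeric(P$reg_head_b)
}

#' Huber regression loss
#'
#' Quadratic within `|r| <= delta`, linear outside, continuous and once
#' differentiable at the transition; averaged over samples.
#'
#' @param y measured values.
#' @param yhat predicted values.
#' @param delta transition point (> 0), default 1 degree Brix.
#' @return scalar loss.
#' @export
reg_loss <- function(y, yhat, delta = 1.0) {
  if (delta <= 0) stopf("delta must be > 0")
  huber_value(yhat - y, delta)
}

#' Generalized-mean pooling
#'
#' `gem(x, p) = (mean(x^p))^(1/p)` per column of a nonnegative matrix;
#' `p = 1` is average pooling and large `p` approaches max pooling.
#'
#' @param m nonnegative numeric matrix (observations x channels) or vector.
#' @param p pooling exponent (>= 1).
#' @param eps stabilizer added before the power (default 0).
#' @return per-column pooled values.
#' @export
gem_pool <- function(m, p, eps = 0) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  drop(colMeans((m + eps)^p)^(1 / p))
}
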