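# Joint select-reconstruct-predict network.
#
# The model couples four parts: (i) spectral-spatial attention (a 3x3 conv
# over band-pooled maps for the spatial mask; a small MLP over the
# band-mean vector for band importances), (ii) a soft, temperature-scaled
# threshold gate over bands, (iii) a two-level encoder-decoder with a skip
# connection reconstructing the full cube through a logistic output, and
# (iv) a compact regression head (depthwise separable conv, efficient
# channel attention, generalized-mean pooling, affine output). Internally
# feature maps are spatial-first (H, W, C); the public cube convention is
# band-first.

#' Construct a joint band-selection model
#'
#' @param n_bands number of spectral channels C.
#' @param K target band budget.
#' @param base_width encoder width F (default 16).
#' @param hidden attention-MLP hidden width (default `max(4, round(C/8))`).
#' @param tau0 initial adaptive threshold (default 0.5).
#' @param T_pass counting temperature for the soft pass count.
#' @param delta Huber transition point in degrees Brix.
#' @param seed seed for weight initialisation.
#' @return object of class `hsi_model`: `params` (named arrays), `config`,
#'   and mutable `state` (`tau`, selection-frequency counters,
#'   `hard_idx`).
#' @export
hsi_model <- function(n_bands, K, base_width = 16L, hidden = NULL,
                      tau0 = 0.5, T_pass = 0.1, delta = 1.0, seed = 1L) {
  if (!is_count(K) || K > n_bands)
    stopf("config error: K must satisfy 1 <= K <= %d", n_bands)
  C <- as.integer(n_bands)
  Fw <- as.integer(base_width)
  hid <- as.integer(hidden %||% max(4L, round(C / 8)))
  eca_k <- {
    t <- round(log2(Fw) / 2 + 0.5)
    k <- if (t %% 2 == 1) t else t + 1
    max(3L, as.integer(k))
  }
  params <- with_seed(seed, list(
    att_sp_W = init_conv(3L, 3L, 2L, 1L), att_sp_b = 0,
    ## the importance head is zero-initialised so that every band starts
    ## at a = 0.5 and early selection is unbiased
    att_W1 = init_dense(C, hid), att_b1 = numeric(hid),
    att_W2 = matrix(0, hid, C), att_b2 = numeric(C),
    rec_e1_W = init_conv(3L, 3L, C, Fw), rec_e1_b = numeric(Fw),
    rec_e2_W = init_conv(3L, 3L, Fw, 2L * Fw), rec_e2_b = numeric(2L * Fw),
    rec_d1_W = init_conv(3L, 3L, 3L * Fw, Fw), rec_d1_b = numeric(Fw),
    rec_o_W = init_conv(3L, 3L, Fw, C), rec_o_b = numeric(C),
    reg_dw_k = array(stats::rnorm(9 * C, sd = sqrt(2 / 9)), c(3L, 3L, C)),
    reg_pw_W = init_dense(C, Fw), reg_pw_b = numeric(Fw),
    reg_eca_w = c(numeric((eca_k - 1) / 2), 1, numeric((eca_k - 1) / 2)),
    reg_gem_p = log(2),               # pooling exponent p = 1 + exp(.) = 3
    reg_head_W = init_dense(Fw, 1L), reg_head_b = 0))
  structure(list(
    params = params,
    config = list(n_bands = C, K = as.integer(K), base_width = Fw,
                  hidden = hid, eca_k = eca_k, T_pass = T_pass,
                  delta = delta, tau0 = tau0),
    state = list(tau = tau0, sel = selection_state(C), hard_idx = NULL)),
    class = "hsi_model")
}

#' @export
print.hsi_model <- function(x, ...) {
  cat(sprintf("<hsi_model> C=%d, K=%d, width=%d, tau=%.3f, %s phase\n",
              x$config$n_bands, x$config$K, x$config$base_width,
              x$state$tau,
              if (is.null(x$state$hard_idx)) "soft" else "hard"))
  invisible(x)
}

param_group <- function(nm) sub("_.*$", "", nm)

trainable_for_stage <- function(params, stage) {
  nms <- names(params)
  switch(as.character(stage),
         "0" = nms,
         "1" = nms[!startsWith(nms, "att_")],
         "2" = nms[startsWith(nms, "reg_")],
         stopf("unknown stage %s", stage))
}

## One-pixel edge-replicate padding for the spatial-attention filter, so
## that spatially uniform inputs produce spatially uniform masks (a zero
## border would break the symmetry at the frame).
pad1_replicate <- function(x) {
  d <- dim(x)
  x[c(1L, seq_len(d[1L]), d[1L]), c(1L, seq_len(d[2L]), d[2L]), ,
    drop = FALSE]
}

## Pad spatial dims to even length (edge replicate); inverse folds the
## padded gradients back. The encoder-decoder needs one factor-2 level.
pad_even_fwd <- function(x) {
  d <- dim(x)
  ph <- d[1] %% 2L
  pw <- d[2] %% 2L
  if (ph) x <- x[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  if (pw) x <- x[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  list(y = x, ph = ph, pw = pw)
}

pad_even_bwd <- function(dy, ph, pw) {
  d <- dim(dy)
  if (pw) {
    dy[, d[2] - 1L, ] <- dy[, d[2] - 1L, ] + dy[, d[2], ]
    dy <- dy[, seq_len(d[2] - 1L), , drop = FALSE]
  }
  d <- dim(dy)
  if (ph) {
    dy[d[1] - 1L, , ] <- dy[d[1] - 1L, , ] + dy[d[1], , ]
    dy <- dy[seq_len(d[1] - 1L), , , drop = FALSE]
  }
  dy
}

## Generalized-mean pooling over rows of a nonnegative hw x F matrix.
gem_fwd <- function(t3, p, eps = 1e-6) {
  tp <- (t3 + eps)^p
  M <- colMeans(tp)
  list(v = M^(1 / p), tp = tp, M = M, p = p, t3 = t3, eps = eps)
}

gem_bwd <- function(cache, dv) {
  hw <- nrow(cache$tp)
  p <- cache$p
  vfac <- dv * cache$v^(1 - p) / hw
  dt3 <- rep(vfac, each = hw) * (cache$tp / (cache$t3 + cache$eps))
  logt <- log(cache$t3 + cache$eps)
  dM_dp <- colMeans(cache$tp * logt)
  dp <- sum(dv * cache$v * (-log(cache$M) / p^2 + dM_dp / (p * cache$M)))
  list(dt3 = dt3, dp = dp)
}

## Full forward pass. x: (H, W, C) array in [0, 1]; hard_gate: optional 0/1
## band gate replacing the soft gate after top-K fixation.
net_forward <- function(P, x, tau, Temp, hard_gate = NULL,
                        need_recon = TRUE, Kbud = 1) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  hw <- H * W
  xmat <- matrix(x, hw, C)

  ## spatial attention: band-wise mean/max maps -> 3x3 conv -> sigmoid
  avgc <- rowMeans(xmat)
  mi <- max.col(xmat, ties.method = "first")
  maxc <- xmat[cbind(seq_len(hw), mi)]
  pooled <- array(c(avgc, maxc), c(H, W, 2L))
  csp <- conv2d_fwd(pad1_replicate(pooled), P$att_sp_W, P$att_sp_b)
  Ms <- sigmoid(as.vector(csp$y[1L + seq_len(H), 1L + seq_len(W), ]))

  ## spectral attention: band means -> MLP -> sigmoid
  s <- colMeans(xmat)
  h1pre <- drop(s %*% P$att_W1) + P$att_b1
  h1 <- relu(h1pre)
  apre <- drop(h1 %*% P$att_W2) + P$att_b2
  a <- sigmoid(apre)

  ## Soft gate: band budget times the normalized selection probabilities,
  ## g_i = K * p_i. Gate mass is competitive across bands and converges to
  ## about 1 on the K retained bands, matching the hard 0/1 gate at
  ## fixation.
  soft <- is.null(hard_gate)
  if (soft) {
    sg <- sigmoid((a - tau) / Temp)
    Zg <- sum(sg)
    g <- pmin(Kbud * sg / Zg, 1)     # capped so gated bands never amplify
  } else {
    sg <- NULL; Zg <- NULL
    g <- hard_gate
  }
  ## Mask and gate are normalized to unit mean before they multiply the
  ## cube: the network then sees a full-strength input from the first
  ## step, and the input scale is continuous from the uniform soft gate
  ## through concentration to the hard fixation (both ends give C/K on
  ## the retained bands).
  m_s <- mean(Ms)
  Msn <- Ms / m_s
  m_g <- mean(g)
  gn <- g / m_g
  xm2 <- xmat * Msn
  xs <- xm2 * rep(gn, each = hw)
  xs_arr <- array(xs, c(H, W, C))

  rec <- NULL
  if (need_recon) {
    pe <- pad_even_fwd(xs_arr)
    c1 <- conv2d_fwd(pe$y, P$rec_e1_W, P$rec_e1_b); e1 <- relu(c1$y)
    p1 <- avgpool2_fwd(e1)
    c2 <- conv2d_fwd(p1, P$rec_e2_W, P$rec_e2_b); e2 <- relu(c2$y)
    u1 <- upsample2_fwd(e2)
    cat1 <- array(c(u1, e1), c(dim(u1)[1], dim(u1)[2],
                               dim(u1)[3] + dim(e1)[3]))
    c3 <- conv2d_fwd(cat1, P$rec_d1_W, P$rec_d1_b); d1 <- relu(c3$y)
    c4 <- conv2d_fwd(d1, P$rec_o_W, P$rec_o_b)
    xhat_p <- sigmoid(c4$y)
    xhat <- xhat_p[seq_len(H), seq_len(W), , drop = FALSE]
    rec <- list(pe = pe, c1 = c1, p1 = p1, c2 = c2, u1 = u1, cat1 = cat1,
                c3 = c3, c4 = c4, xhat_p = xhat_p, xhat = xhat)
  }

  ## regression head
  cdw <- dwconv_fwd(xs_arr, P$reg_dw_k)
  t1 <- matrix(cdw$y, hw, C)
  t2pre <- t1 %*% P$reg_pw_W + rep(P$reg_pw_b, each = hw)
  t2 <- relu(t2pre)
  s2 <- colMeans(t2)
  ce <- conv1d_fwd(s2, P$reg_eca_w)
  z <- sigmoid(ce$y)
  t3 <- t2 * rep(z, each = hw)
  p_gem <- 1 + exp(as.numeric(P$reg_gem_p))
  gem <- gem_fwd(t3, p_gem)
  yhat <- as.numeric(gem$v %*% P$reg_head_W) + as.numeric(P$reg_head_b)

  list(H = H, W = W, C = C, hw = hw, xmat = xmat, csp = csp, Ms = Ms,
       m_s = m_s, Msn = Msn, m_g = m_g, gn = gn,
       s = s, h1pre = h1pre, h1 = h1, a = a, g = g, sg = sg, Zg = Zg,
       Kbud = Kbud, soft = soft,
       Temp = Temp, tau = tau, xm2 = xm2, xs_arr = xs_arr, rec = rec,
       cdw = cdw, t1 = t1, t2pre = t2pre, t2 = t2, ce = ce, z = z,
       t3 = t3, gem = gem, yhat = yhat,
       xhat = if (need_recon) rec$xhat else NULL)
}

## Backward pass. dxhat: gradient on the reconstruction (already weighted);
## dyhat: scalar gradient on the prediction; da_extra: direct gradient on
## the importance vector (band-budget penalty). Returns parameter grads and
## the total gradient reaching `a`.
net_backward <- function(P, fw, dxhat = NULL, dyhat = 0, da_extra = NULL) {
  H <- fw$H; W <- fw$W; C <- fw$C; hw <- fw$hw
  G <- list()
  dxs <- matrix(0, hw, C)

  if (dyhat != 0) {
    G$reg_head_W <- matrix(fw$gem$v * dyhat, ncol = 1L)
    G$reg_head_b <- dyhat
    dv <- as.vector(P$reg_head_W) * dyhat
    gb <- gem_bwd(fw$gem, dv)
    G$reg_gem_p <- gb$dp * exp(P$reg_gem_p)
    dt3 <- gb$dt3
    dz <- colSums(dt3 * fw$t2)
    dt2 <- dt3 * rep(fw$z, each = hw)
    eb <- conv1d_bwd(fw$ce, P$reg_eca_w, dz * fw$z * (1 - fw$z))
    G$reg_eca_w <- eb$dw
    dt2 <- dt2 + rep(eb$ds / hw, each = hw)
    dt2pre <- dt2 * (fw$t2pre > 0)
    G$reg_pw_W <- crossprod(fw$t1, dt2pre)
    G$reg_pw_b <- colSums(dt2pre)
    dt1 <- dt2pre %*% t(P$reg_pw_W)
    db <- dwconv_bwd(fw$cdw, P$reg_dw_k, array(dt1, c(H, W, C)))
    G$reg_dw_k <- db$dk
    dxs <- dxs + matrix(db$dx, hw, C)
  }

  if (!is.null(dxhat)) {
    r <- fw$rec
    dxp <- array(0, dim(r$xhat_p))
    dxp[seq_len(H), seq_len(W), ] <- dxhat
    dc4 <- dxp * r$xhat_p * (1 - r$xhat_p)
    b4 <- conv2d_bwd(r$c4, P$rec_o_W, dc4)
    G$rec_o_W <- b4$dW; G$rec_o_b <- b4$db
    dd1 <- b4$dx * (r$c3$y > 0)
    b3 <- conv2d_bwd(r$c3, P$rec_d1_W, dd1)
    G$rec_d1_W <- b3$dW; G$rec_d1_b <- b3$db
    F2 <- dim(r$u1)[3]
    du1 <- b3$dx[, , seq_len(F2), drop = FALSE]
    de1a <- b3$dx[, , (F2 + 1):dim(b3$dx)[3], drop = FALSE]
    de2 <- upsample2_bwd(du1) * (r$c2$y > 0)
    b2 <- conv2d_bwd(r$c2, P$rec_e2_W, de2)
    G$rec_e2_W <- b2$dW; G$rec_e2_b <- b2$db
    de1 <- (de1a + avgpool2_bwd(b2$dx)) * (r$c1$y > 0)
    b1 <- conv2d_bwd(r$c1, P$rec_e1_W, de1)
    G$rec_e1_W <- b1$dW; G$rec_e1_b <- b1$db
    dxs <- dxs + matrix(pad_even_bwd(b1$dx, r$pe$ph, r$pe$pw), hw, C)
  }

  ## through the normalized gate and mask into importances and mask
  dxm2 <- dxs * rep(fw$gn, each = hw)
  dgn <- colSums(dxs * fw$xm2)
  dMsn <- rowSums(dxm2 * fw$xmat)
  ## unit-mean normalization Jacobians: v = u / mean(u)
  dg <- (dgn - sum(dgn * fw$gn) / C) / fw$m_g
  dMs <- (dMsn - sum(dMsn * fw$Msn) / hw) / fw$m_s
  da <- numeric(C)
  if (fw$soft) {
    ## g_j = min(K * s_j / Z, 1) with s_j = sigma((a_j - tau)/T), Z = sum(s):
    ## da_j = (s_j'(.)/T) * (K/Z) * (dg_j [uncapped] - sum_i dg_i s_i / Z)
    open <- fw$g < 1
    dg_eff <- dg * open
    sprime <- fw$sg * (1 - fw$sg) / fw$Temp
    da <- sprime * (fw$Kbud / fw$Zg) *
      (open * dg - sum(dg_eff * fw$sg) / fw$Zg)
  }
  if (!is.null(da_extra)) da <- da + da_extra

  ## spectral attention
  dapre <- da * fw$a * (1 - fw$a)
  G$att_W2 <- outer(fw$h1, dapre)
  G$att_b2 <- dapre
  dh1 <- drop(P$att_W2 %*% dapre) * (fw$h1pre > 0)
  G$att_W1 <- outer(fw$s, dh1)
  G$att_b1 <- dh1

  ## spatial attention (gradient embedded into the padded frame)
  dms_pre <- dMs * fw$Ms * (1 - fw$Ms)
  dfull <- array(0, c(H + 2L, W + 2L, 1L))
  dfull[1L + seq_len(H), 1L + seq_len(W), 1L] <- dms_pre
  bsp <- conv2d_bwd(fw$csp, P$att_sp_W, dfull, need_dx = FALSE)
  G$att_sp_W <- bsp$dW
  G$att_sp_b <- bsp$db
  list(grads = G, da = da, dMs = dMs)
}

## Loss + gradients for one sample under the scheduled weights.
## x: (H, W, C) normalized cube; y: label; wts: list(alpha, beta, lambda).
joint_loss_grads <- function(model, x, y, wts, Temp, hard_gate = NULL,
                             need_recon = TRUE) {
  P <- model$params
  cfg <- model$config
  tau <- model$state$tau
  fw <- net_forward(P, x, tau, Temp, hard_gate = hard_gate,
                    need_recon = need_recon, Kbud = cfg$K)
  L_rec <- 0; dxhat <- NULL
  if (need_recon) {
    err <- fw$xhat - x
    L_rec <- mean(err^2)
    if (wts$alpha != 0) dxhat <- wts$alpha * 2 * err / length(err)
  }
  r <- fw$yhat - y
  L_reg <- huber_value(r, cfg$delta)
  dyhat <- wts$beta * huber_grad(r, cfg$delta)
  L_pass <- 0; da_extra <- NULL
  if (fw$soft) {
    sig <- sigmoid((fw$a - tau) / cfg$T_pass)
    Ks <- sum(sig)
    L_pass <- pass_loss(Ks, cfg$K)
    da_extra <- wts$lambda * (Ks - cfg$K) * sig * (1 - sig) / cfg$T_pass
  }
  bw <- net_backward(P, fw, dxhat = dxhat, dyhat = dyhat,
                     da_extra = da_extra)
  list(L_rec = L_rec, L_reg = L_reg, L_pass = L_pass,
       total = wts$alpha * L_rec + wts$beta * L_reg + wts$lambda * L_pass,
       yhat = fw$yhat, a = fw$a, grads = bw$grads, fw = fw)
}

huber_value <- function(r, delta) {
  ar <- abs(r)
  mean(ifelse(ar <= delta, 0.5 * r^2, delta * ar - 0.5 * delta^2))
}

huber_grad <- function(r, delta) {
  ifelse(abs(r) <= delta, r, delta * sign(r))
}
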