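# Structural and gradient checks on the network branches. The analytic
# backward pass is validated against central finite differences, which is
# the ground truth the optimiser relies on.

toy_model <- function(C = 6, K = 3, seed = 3) {
  m <- hsi_model(C, K = K, base_width = 4, hidden = 4, seed = seed)
  ## non-degenerate importance head for gradient tests
  m$params$att_W2 <- hsiband:::with_seed(seed + 1,
    matrix(rnorm(4 * C, sd = 0.3), 4, C))
  m
}

toy_cube <- function(C = 6, H = 6, W = 6, seed = 1) {
  hsiband:::with_seed(seed, array(runif(C * H * W), c(C, H, W)))
}

test_that("spatial attention masks are in (0,1) with the cube's spatial shape", {
  m <- toy_model()
  for (dims in list(c(6, 5, 7), c(6, 4, 4))) {
    cube <- toy_cube(dims[1], dims[2], dims[3])
    Ms <- spatial_attention(cube, m)
    expect_equal(dim(Ms), dims[2:3])
    expect_true(all(Ms > 0 & Ms < 1))
  }
  ## spatially constant cube gives a spatially constant mask
  cc <- array(rep(runif(6), 5 * 5), c(6, 5, 5))
  Msc <- spatial_attention(cc, toy_model())
  expect_lt(diff(range(Msc)), 1e-12)
})

test_that("spectral attention depends on the cube only through band means", {
  m <- toy_model()
  cube <- toy_cube()
  a <- spectral_attention(cube, m)
  expect_length(a, 6)
  expect_true(all(a > 0 & a < 1))
  ## shuffle pixels within each band: identical pooled means, identical a
  shuffled <- cube
  perm <- hsiband:::with_seed(9, sample(36))
  for (b in 1:6) shuffled[b, , ] <- matrix(as.vector(cube[b, , ])[perm], 6, 6)
  expect_equal(spectral_attention(shuffled, m), a, tolerance = 1e-12)
})

test_that("spectral attention input gradient matches finite differences", {
  m <- toy_model(C = 4)
  cube <- toy_cube(C = 4, H = 3, W = 3, seed = 5)
  da <- hsiband:::with_seed(7, rnorm(4))
  an <- hsiband:::spectral_attention_vjp(cube, m, da)
  eps <- 1e-5
  idx <- hsiband:::with_seed(8, sample(length(cube), 12))
  for (i in idx) {
    cp <- cube; cp[i] <- cube[i] + eps
    cm <- cube; cm[i] <- cube[i] - eps
    num <- sum(da * (spectral_attention(cp, m) -
                     spectral_attention(cm, m))) / (2 * eps)
    expect_equal(an[i], num, tolerance = 1e-4)
  }
})

test_that("full joint backward pass matches finite differences", {
  set.seed(42)
  m <- toy_model(C = 6, K = 3, seed = 3)
  x <- toy_cube(6, 6, 6, seed = 42)
  xi <- aperm(x, c(2, 3, 1))
  y <- 10
  wts <- list(alpha = 0.7, beta = 0.9, lambda = 0.05)
  Temp <- 0.5
  res <- hsiband:::joint_loss_grads(m, xi, y, wts, Temp)
  loss_at <- function(params) {
    fw <- hsiband:::net_forward(params, xi, m$state$tau, Temp,
                                Kbud = m$config$K)
    L_rec <- mean((fw$xhat - xi)^2)
    L_reg <- hsiband:::huber_value(fw$yhat - y, m$config$delta)
    sig <- hsiband:::sigmoid((fw$a - m$state$tau) / m$config$T_pass)
    wts$alpha * L_rec + wts$beta * L_reg +
      wts$lambda * pass_loss(sum(sig), m$config$K)
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    p0 <- m$params[[nm]]
    probe <- hsiband:::with_seed(5, sample(length(p0), min(4, length(p0))))
    for (i in probe) {
      pp <- m$params; pp[[nm]][i] <- p0[i] + eps
      pm <- m$params; pm[[nm]][i] <- p0[i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(as.vector(res$grads[[nm]])[i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("gradients from both branches reach the importance vector", {
  m <- toy_model()
  xi <- aperm(toy_cube(), c(2, 3, 1))
  fw <- hsiband:::net_forward(m$params, xi, m$state$tau, 0.5,
                              Kbud = m$config$K)
  only_rec <- hsiband:::net_backward(m$params, fw,
                                     dxhat = array(1, dim(fw$xhat)) / 100)
  only_reg <- hsiband:::net_backward(m$params, fw, dyhat = 1)
  expect_gt(sqrt(sum(only_rec$da^2)), 0)
  expect_gt(sqrt(sum(only_reg$da^2)), 0)
})

test_that("reconstruction outputs are bounded and shape-preserving", {
  m <- toy_model()
  for (dims in list(c(6, 6), c(5, 7))) {     # odd sizes pad internally
    cube <- toy_cube(6, dims[1], dims[2])
    xh <- reconstruct(m, cube)
    expect_equal(dim(xh$values), c(6L, dims))
    expect_true(all(xh$values > 0 & xh$values < 1))
  }
  ## zero final-layer weights pin the logistic output at 0.5
  mz <- toy_model()
  mz$params$rec_o_W[] <- 0
  mz$params$rec_o_b[] <- 0
  xh <- reconstruct(mz, toy_cube())
  expect_true(all(abs(xh$values - 0.5) < 1e-12))
})

test_that("rec_loss is the voxel-mean squared error", {
  x <- toy_cube(3, 4, 4, 1)
  expect_equal(rec_loss(x, x), 0)
  expect_equal(rec_loss(x + 0.1, x), 0.01, tolerance = 1e-12)
  expect_equal(rec_loss(x + 0.1, x), recon_metrics(x, x + 0.1)$mse,
               tolerance = 1e-12)
  expect_error(rec_loss(x, toy_cube(3, 4, 5, 1)), "shape")
})

test_that("generalized-mean pooling interpolates mean and max", {
  mmap <- matrix(hsiband:::with_seed(3, runif(50, 0.02, 0.2)), 25, 2)
  expect_equal(gem_pool(mmap, p = 1), colMeans(mmap), tolerance = 1e-12)
  expect_lt(max(abs(gem_pool(mmap, p = 64) - apply(mmap, 2, max))), 1e-2)
  ## monotone in p
  expect_true(all(gem_pool(mmap, 4) >= gem_pool(mmap, 2) - 1e-12))
})

test_that("SSC prediction is finite and translation-invariant for constants", {
  m <- toy_model()
  cube <- array(0.4, c(6, 8, 8))
  y1 <- predict_ssc(m, cube)
  expect_true(is.finite(y1))
  ## a spatially constant cube is invariant to any spatial translation,
  ## so the global-pooled prediction must not change
  y2 <- predict_ssc(m, cube[, c(3:8, 1:2), ])
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("huber regression loss matches its closed forms", {
  expect_equal(reg_loss(1, 1, delta = 1), 0)
  expect_equal(reg_loss(0, 0.5, delta = 1), 0.125)
  expect_equal(reg_loss(0, 2, delta = 1), 1.5)
  ## continuity and once-differentiability at the transition
  eps <- 1e-7
  expect_equal(reg_loss(0, 1 - eps, 1), reg_loss(0, 1 + eps, 1),
               tolerance = 1e-6)
  g1 <- (reg_loss(0, 1 - eps, 1) - reg_loss(0, 1 - 3 * eps, 1)) / (2 * eps)
  g2 <- (reg_loss(0, 1 + 3 * eps, 1) - reg_loss(0, 1 + eps, 1)) / (2 * eps)
  expect_equal(g1, g2, tolerance = 1e-5)
  expect_error(reg_loss(1, 1, delta = 0), "delta")
})
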