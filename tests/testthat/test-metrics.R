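rand_cube <- function(C, H, W, seed) {
  hsiband:::with_seed(seed, array(runif(C * H * W), c(C, H, W)))
}

test_that("reconstruction metrics satisfy their identities", {
  x <- rand_cube(3, 4, 4, 1)
  m <- recon_metrics(x, x)
  expect_equal(m$mae, 0); expect_equal(m$mse, 0)
  expect_true(is.infinite(m$psnr))
  expect_equal(m$ssim, 1, tolerance = 1e-9)
  expect_equal(m$scc, 1, tolerance = 1e-9)
  expect_equal(m$sam, 0, tolerance = 1e-6)

  ## constant offset: closed forms for MSE and PSNR
  x2 <- rand_cube(3, 4, 4, 2) * 0.5            # room for the offset
  off <- recon_metrics(x2, x2 + 0.1)
  expect_equal(off$mse, 0.01, tolerance = 1e-12)
  expect_equal(off$psnr, -20 * log10(0.1), tolerance = 1e-9)
  expect_equal(off$mae, 0.1, tolerance = 1e-12)
})

test_that("spectral angle matches the hand-computed toy", {
  ## every pixel has spectrum (1,0) in x and (1,1) in the reconstruction
  x <- array(0, c(2, 2, 2)); x[1, , ] <- 1
  r <- array(1, c(2, 2, 2))
  expect_equal(recon_metrics(x, r)$sam, 45, tolerance = 1e-9)
})

test_that("recon metrics agree with a double-loop oracle on 4x4x3 toys", {
  for (seed in 1:3) {
    x <- rand_cube(3, 4, 4, seed)
    r <- rand_cube(3, 4, 4, seed + 100)
    m <- recon_metrics(x, r)
    ## straightforward reimplementation
    n <- length(x)
    mse <- 0; mae <- 0
    for (i in seq_len(n)) {
      mse <- mse + (r[i] - x[i])^2 / n
      mae <- mae + abs(r[i] - x[i]) / n
    }
    C1 <- 1e-4; C2 <- 9e-4
    ssims <- numeric(3)
    for (b in 1:3) {
      a <- as.vector(x[b, , ]); bb <- as.vector(r[b, , ])
      mx <- mean(a); my <- mean(bb)
      vx <- mean((a - mx)^2); vy <- mean((bb - my)^2)
      cxy <- mean((a - mx) * (bb - my))
      ssims[b] <- (2 * mx * my + C1) * (2 * cxy + C2) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
    sccs <- sams <- numeric(16)
    k <- 0
    for (h in 1:4) for (w in 1:4) {
      k <- k + 1
      sx <- x[, h, w]; sr <- r[, h, w]
      sccs[k] <- if (sd(sx) > 0 && sd(sr) > 0) cor(sx, sr) else 0
      sams[k] <- acos(sum(sx * sr) / sqrt(sum(sx^2) * sum(sr^2))) * 180 / pi
    }
    expect_equal(m$mse, mse, tolerance = 1e-10)
    expect_equal(m$mae, mae, tolerance = 1e-10)
    expect_equal(m$psnr, 10 * log10(1 / mse), tolerance = 1e-10)
    expect_equal(m$ssim, mean(ssims), tolerance = 1e-10)
    expect_equal(m$scc, mean(sccs), tolerance = 1e-10)
    expect_equal(m$sam, mean(sams), tolerance = 1e-10)
  }
})

test_that("metric bounds hold under fuzzing", {
  for (seed in 1:20) {
    x <- rand_cube(4, 3, 5, seed)
    r <- rand_cube(4, 3, 5, seed + 1000)
    m <- recon_metrics(x, r)
    expect_gte(m$mse, 0)
    expect_true(m$ssim >= -1 && m$ssim <= 1)
    expect_true(m$scc >= -1 && m$scc <= 1)
    expect_gte(m$sam, 0)
  }
  expect_error(recon_metrics(rand_cube(2, 3, 3, 1), rand_cube(2, 3, 4, 1)),
               "shape")
})

test_that("regression metrics match their definitions", {
  y <- c(1, 2, 3); yh <- c(1, 2, 4)
  m <- reg_metrics(y, yh)
  expect_equal(m$r2, 0.5)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$rpd * m$rmse, sd(y), tolerance = 1e-12)
  perfect <- reg_metrics(y, y)
  expect_equal(perfect$rmse, 0); expect_equal(perfect$r2, 1)
  expect_equal(reg_metrics(y, rep(mean(y), 3))$r2, 0)
  expect_error(reg_metrics(rep(1, 3), c(1, 2, 3)), "variance")
  ## RPD * RMSE = SD(y) identically under fuzzing
  for (seed in 1:10) {
    yy <- hsiband:::with_seed(seed, rnorm(20, 10, 1.4))
    ph <- hsiband:::with_seed(seed + 50, yy + rnorm(20, 0, 0.5))
    mm <- reg_metrics(yy, ph)
    expect_equal(mm$rpd * mm$rmse, sd(yy), tolerance = 1e-10)
  }
})

test_that("band-to-wavelength mapping is the uniform instrument map", {
  expect_equal(band_to_wavelength(0, 176), 404.7)
  expect_equal(band_to_wavelength(175, 176), 1010.8)
  ## linearity around the midpoint
  expect_equal(mean(band_to_wavelength(c(87, 88), 176)),
               mean(c(404.7, 1010.8)))
  expect_error(band_to_wavelength(176, 176), "out of range")
})

test_that("baseline selectors return K distinct indices", {
  expect_identical(baseline_select("random", K = 10, n_bands = 10, seed = 1),
                   0:9)
  r1 <- baseline_select("random", K = 4, n_bands = 12, seed = 5)
  expect_identical(r1, baseline_select("random", K = 4, n_bands = 12,
                                       seed = 5))
  expect_length(unique(r1), 4L)
  ## variance method recovers bands with inflated variance
  cubes <- lapply(1:6, function(i) {
    arr <- rand_cube(10, 4, 4, i) * 0.05
    arr[c(2, 5, 8), , ] <- arr[c(2, 5, 8), , ] * 20
    arr
  })
  v <- baseline_select("variance", K = 6, n_bands = 10, cubes = cubes)
  expect_gte(length(intersect(v, c(1, 4, 7))), 2L)
  expect_error(baseline_select("random", K = 11, n_bands = 10), "exceeds")
})

test_that("stability reports track subset evolution", {
  subs <- list(c(0, 1, 2), c(1, 2, 3), c(1, 2, 3))
  rep_ <- stability_report(subs, final_subset = c(1, 2, 3),
                           per_split_frequencies = list(
                             train = c(5, 9, 9, 3), val = c(2, 4, 4, 1)))
  expect_equal(rep_$jaccard_prev, c(NA, 0.5, 1))
  expect_equal(rep_$overlap_k, c(2 / 3, 1, 1))
  expect_equal(max(rep_$normalized_frequencies$train), 1)
  expect_equal(rep_$normalized_frequencies$val, c(2, 4, 4, 1) / 4)
  expect_identical(stability_report(list(c(0, 1)), c(2, 3))$overlap_k, 0)
})

test_that("band entropy matches closed-form histograms", {
  const <- array(0.4, c(2, 4, 4))
  expect_equal(band_entropy(const, 16), c(0, 0))
  ## one band exactly uniform over 16 bins
  u <- array(0, c(1, 4, 4))
  u[1, , ] <- (seq_len(16) - 0.5) / 16
  expect_equal(band_entropy(u, 16), 4)
  ## entropy depends only on the histogram mass, not bin identity
  v <- array(0, c(1, 4, 4)); v[1, , ] <- rev((seq_len(16) - 0.5) / 16)
  expect_equal(band_entropy(v, 16), band_entropy(u, 16))
})
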