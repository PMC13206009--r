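## Small summary fixtures built directly (no cubes needed).
mk_sum <- function(id, ssc, intensity, spec) {
  structure(list(id = id, ssc_label = ssc, mean_intensity = intensity,
                 mean_spectrum = spec), class = "sample_summary")
}

rand_sums <- function(n, C = 5, seed = 1) {
  hsiband:::with_seed(seed, lapply(seq_len(n), function(i)
    mk_sum(paste0("s", i), rnorm(1, 10, 1.4), runif(1, 0.1, 0.3),
           runif(C))))
}

test_that("sample summaries satisfy their algebraic identity", {
  cube <- hyper_cube(array(runif(4 * 3 * 3), c(4, 3, 3)))
  sm <- summarize_sample(cube, 10.5, id = "x")
  expect_equal(sm$mean_intensity, mean(sm$mean_spectrum))
  cc <- hyper_cube(array(0.3, c(4, 3, 3)))
  sc <- summarize_sample(cc, 9)
  expect_equal(sc$mean_intensity, 0.3)
  expect_equal(sc$mean_spectrum, rep(0.3, 4))
  bright <- array(0.1, c(4, 3, 3)); bright[2, , ] <- 0.9
  sb <- summarize_sample(hyper_cube(bright), 9)
  expect_equal(which.max(sb$mean_spectrum), 2L)
})

test_that("quantile bins are balanced, order-preserving and tie-stable", {
  b <- quantile_bins(c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6), 5)
  expect_equal(tabulate(b + 1L, 5), rep(2L, 5))
  expect_equal(b[order(c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6))],
               rep(0:4, each = 2))
  tied <- quantile_bins(rep(1, 7), 3)
  expect_lte(diff(range(tabulate(tied + 1L, 3))), 1L)
  expect_equal(tied[1:3], c(0L, 0L, 0L))    # stable order fills bins in turn
  expect_equal(quantile_bins(rnorm(6), 1), rep(0L, 6))
})

test_that("split cost components match a brute-force evaluation", {
  ## 6 samples, 2 per subset; oracle computes each term from definitions
  sums <- list(
    mk_sum("a", 8,  0.10, c(0.1, 0.2)), mk_sum("b", 9,  0.15, c(0.2, 0.3)),
    mk_sum("c", 10, 0.20, c(0.3, 0.4)), mk_sum("d", 11, 0.25, c(0.4, 0.5)),
    mk_sum("e", 12, 0.30, c(0.5, 0.6)), mk_sum("f", 13, 0.35, c(0.6, 0.7)))
  assign <- c("train", "val", "train", "test", "val", "test")
  got <- split_cost(assign, sums, n_bins = 2)

  lab <- c(8, 9, 10, 11, 12, 13); intens <- seq(0.10, 0.35, by = 0.05)
  spec <- rbind(c(.1, .2), c(.2, .3), c(.3, .4), c(.4, .5), c(.5, .6),
                c(.6, .7))
  bins <- ifelse(lab <= 10, 1, 2)            # 2 quantile bins of 3
  subs <- list(train = c(1, 3), val = c(2, 5), test = c(4, 6))
  hist_of <- function(ix) tabulate(bins[ix], 2) + 1e-12
  jsd <- function(p, q) {
    p <- p / sum(p); q <- q / sum(q); m <- (p + q) / 2
    kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
    (kl(p, m) + kl(q, m)) / 2
  }
  hs <- lapply(subs, hist_of)
  exp_hist <- mean(c(jsd(hs[[1]], hs[[2]]), jsd(hs[[1]], hs[[3]]),
                     jsd(hs[[2]], hs[[3]])))
  mom <- 0
  for (ix in subs) {
    mom <- mom + (abs(mean(lab[ix]) - mean(lab)) +
                  abs(sd(lab[ix]) - sd(lab))) / sd(lab) +
                 (abs(mean(intens[ix]) - mean(intens)) +
                  abs(sd(intens[ix]) - sd(intens))) / sd(intens)
  }
  spc <- 0
  scale <- pmax(apply(spec, 2, sd), 1e-12)
  for (ix in subs) {
    dev <- (colMeans(spec[ix, , drop = FALSE]) - colMeans(spec)) / scale
    spc <- spc + sqrt(mean(dev^2))
  }
  expect_equal(got$histogram, exp_hist, tolerance = 1e-12)
  expect_equal(got$moments, mom, tolerance = 1e-12)
  expect_equal(got$spectral, spc, tolerance = 1e-12)
  expect_equal(got$total, exp_hist + mom + spc, tolerance = 1e-12)
})

test_that("degenerate assignments and symmetries behave", {
  sums <- rand_sums(9)
  a <- rep(c("train", "val", "test"), 3)
  ## swapping two samples with identical summaries leaves the cost unchanged
  sums2 <- sums
  sums2[[1]] <- sums[[4]]; sums2[[4]] <- sums[[1]]
  c1 <- split_cost(a, sums)
  a2 <- a; a2[c(1, 4)] <- a[c(4, 1)]
  c2 <- split_cost(a2, sums2)
  expect_equal(c1$total, c2$total)
  expect_true(is.infinite(split_cost(rep("train", 9), sums)$total))
})

test_that("balanced split partitions, conserves sizes and never worsens", {
  sums <- rand_sums(60, seed = 3)
  sp <- balanced_split(sums, seed = 2, max_iter = 500)
  expect_equal(sum(sp$sizes), 60)
  expect_equal(sort(unique(sp$assignment$subset)),
               c("test", "train", "val"))
  expect_equal(nrow(sp$assignment), 60L)
  expect_false(any(duplicated(sp$assignment$id)))
  expect_true(all(diff(sp$cost_trace) < 0))      # strictly improving accepts
  expect_lte(sp$cost$total, sp$initial_cost$total)
  expect_error(balanced_split(sums, ratio = c(1, 0, 1)), "config error")
})

test_that("refined splits balance a bimodal label set like the exhaustive optimum", {
  ## 12 samples, bimodal labels; 4/4/4 subsets are enumerable and can be
  ## balanced exactly (two samples from each mode per subset)
  set.seed(10)
  labs <- c(rnorm(6, 8, 0.2), rnorm(6, 12, 0.2))
  sums <- lapply(seq_along(labs), function(i)
    mk_sum(paste0("s", i), labs[i], 0.2 + 0.001 * i, rep(0.2, 3)))
  sp <- balanced_split(sums, ratio = c(1, 1, 1), seed = 1, max_iter = 3000)
  gm <- mean(labs); gs <- sd(labs)
  for (ss in c("train", "val", "test")) {
    ix <- sp$assignment$subset == ss
    expect_lt(abs(mean(labs[ix]) - gm), 0.2 * gs)
  }
  ## exhaustive oracle: the best 4/4/4 split also satisfies the property,
  ## and the refined cost is close to the exhaustive optimum
  combs <- combn(12, 4)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    tr <- combs[, j]
    rest <- setdiff(1:12, tr)
    v3 <- combn(rest, 4)
    for (k in seq_len(ncol(v3))) {
      a <- rep("test", 12); a[tr] <- "train"; a[v3[, k]] <- "val"
      cst <- split_cost(a, sums)$total
      if (cst < best) { best <- cst; besta <- a }
    }
  }
  for (ss in c("train", "val", "test"))
    expect_lt(abs(mean(labs[besta == ss]) - gm), 0.2 * gs)
  expect_lte(sp$cost$total, best * 2 + 1e-9)
})

test_that("subset statistics concentrate for exchangeable samples", {
  sums <- rand_sums(500, seed = 9)
  sp <- balanced_split(sums, seed = 4, max_iter = 1500)
  labs <- vapply(sums, function(s) s$ssc_label, 1)
  gm <- mean(labs); gs <- sd(labs)
  for (ss in c("train", "val", "test")) {
    ix <- sp$assignment$subset == ss
    expect_lt(abs(mean(labs[ix]) - gm), 0.15 * gs)
  }
})
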