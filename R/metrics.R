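#' Reconstruction fidelity metrics
#'
#' Computes MAE, MSE, PSNR, band-averaged SSIM, the mean pixelwise spectral
#' Pearson correlation (SCC), and the mean spectral angle (SAM, degrees)
#' between a ground-truth cube and a reconstruction, both on the normalized
#' `[0, 1]` reflectance scale.
#'
#' PSNR uses `10 * log10(MAX^2 / MSE)` with `MAX = 1`; an exact
#' reconstruction reports `Inf`. SSIM is computed per band from global
#' band statistics with stabilizers `C1 = 0.01^2`, `C2 = 0.03^2` (dynamic
#' range 1) and averaged over bands; `ssim_window = "gaussian"` instead
#' averages an 11x11 Gaussian-window SSIM map per band. Pixels with a
#' zero-variance spectrum contribute 0 to SCC; zero-norm spectra contribute
#' 0 degrees to SAM.
#'
#' @param x ground-truth [hyper_cube()] or band-first array.
#' @param xhat reconstructed cube of the same shape.
#' @param ssim_window `"global"` (default) or `"gaussian"`.
#' @return list of class `recon_metrics`: `mae`, `mse`, `psnr`, `ssim`,
#'   `scc`, `sam`.
#' @export
recon_metrics <- function(x, xhat, ssim_window = c("global", "gaussian")) {
  ssim_window <- match.arg(ssim_window)
  xv <- if (inherits(x, "hyper_cube")) x$values else x
  rv <- if (inherits(xhat, "hyper_cube")) xhat$values else xhat
  if (!all(dim(xv) == dim(rv))) stopf("shape mismatch between cubes")
  d <- dim(xv)
  C <- d[1]
  err <- rv - xv
  mse <- mean(err^2)
  mae <- mean(abs(err))
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)

  C1 <- 0.01^2; C2 <- 0.03^2
  ssim_band <- function(a, b) {
    mx <- mean(a); my <- mean(b)
    vx <- mean((a - mx)^2); vy <- mean((b - my)^2)
    cxy <- mean((a - mx) * (b - my))
    ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  if (ssim_window == "global") {
    ssim <- mean(vapply(seq_len(C), function(b)
      ssim_band(xv[b, , ], rv[b, , ]), 1))
  } else {
    ssim <- mean(vapply(seq_len(C), function(b)
      ssim_gaussian_band(xv[b, , ], rv[b, , ], C1, C2), 1))
  }

  ## pixelwise spectral statistics on the C x HW matrix view
  xm <- matrix(xv, C)
  rm_ <- matrix(rv, C)
  mx <- colMeans(xm); mr <- colMeans(rm_)
  xc <- xm - rep(mx, each = C)
  rc <- rm_ - rep(mr, each = C)
  sx <- colSums(xc^2); sr <- colSums(rc^2)
  num <- colSums(xc * rc)
  den <- sqrt(sx * sr)
  scc_pix <- ifelse(den > 0, num / den, 0)
  scc <- mean(scc_pix)

  nx <- sqrt(colSums(xm^2)); nr <- sqrt(colSums(rm_^2))
  dot <- colSums(xm * rm_)
  cosang <- ifelse(nx * nr > 0, pmin(pmax(dot / (nx * nr), -1), 1), 1)
  sam <- mean(acos(cosang)) * 180 / pi

  structure(list(mae = mae, mse = mse, psnr = psnr, ssim = ssim,
                 scc = scc, sam = sam), class = "recon_metrics")
}

## Gaussian-window SSIM (11x11, sigma 1.5) averaged over one band.
ssim_gaussian_band <- function(a, b, C1, C2) {
  g <- stats::dnorm(-5:5, sd = 1.5)
  g <- g / sum(g)
  blur <- function(m) {
    m2 <- apply(m, 2, function(col) stats::filter(col, g, sides = 2))
    m3 <- t(apply(m2, 1, function(row) stats::filter(row, g, sides = 2)))
    m3
  }
  mu_a <- blur(a); mu_b <- blur(b)
  va <- blur(a * a) - mu_a^2
  vb <- blur(b * b) - mu_b^2
  cab <- blur(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s, na.rm = TRUE)
}

#' SSC regression metrics
#'
#' MAE, RMSE, coefficient of determination and residual predictive
#' deviation for measured versus predicted labels:
#' `R2 = 1 - SSres / SStot`, `RPD = SD(y) / RMSE` with the sample standard
#' deviation of the measured values.
#'
#' @param y measured SSC values (length >= 2).
#' @param yhat predicted SSC values.
#' @return list of class `reg_metrics`: `mae`, `rmse`, `r2`, `rpd`.
#' @export
reg_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("y and yhat lengths differ")
  if (length(y) < 2) stopf("need at least 2 samples")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stopf("zero label variance: R2 and RPD undefined")
  r <- yhat - y
  rmse <- sqrt(mean(r^2))
  structure(list(mae = mean(abs(r)), rmse = rmse,
                 r2 = 1 - sum(r^2) / sstot,
                 rpd = if (rmse > 0) stats::sd(y) / rmse else Inf),
            class = "reg_metrics")
}

#' Band index to wavelength mapping
#'
#' Uniform linear map over the instrument range: index 0 maps to the range
#' minimum, index `n_bands - 1` to the maximum.
#'
#' @param index 0-based band index (vectorised).
#' @param n_bands total band count.
#' @param wavelength_range length-2 nm range, default `c(404.7, 1010.8)`.
#' @return wavelength(s) in nm.
#' @export
band_to_wavelength <- function(index, n_bands,
                               wavelength_range = c(404.7, 1010.8)) {
  if (any(index < 0 | index > n_bands - 1))
    stopf("band index out of range [0, %d]", n_bands - 1)
  wavelength_range[1] +
    index * diff(wavelength_range) / (n_bands - 1)
}

#' Baseline band selectors
#'
#' Reference selectors for ablation: `"random"` draws K distinct bands
#' under `seed`; `"variance"` ranks bands by their per-band variance over
#' the training cubes; `"frequency"` ranks by accumulated selection
#' frequencies (pass `frequency`, and optionally `a_mean` for tie-breaks).
#'
#' @param method one of `"random"`, `"variance"`, `"frequency"`.
#' @param K number of bands to keep.
#' @param n_bands total band count.
#' @param cubes list of band-first arrays or [hyper_cube()]s (variance
#'   method).
#' @param frequency selection-frequency counts (frequency method).
#' @param a_mean optional running-mean importance for frequency tie-breaks.
#' @param seed seed for the random method.
#' @return sorted 0-based integer vector of K distinct band indices.
#' @export
baseline_select <- function(method = c("random", "variance", "frequency"),
                            K, n_bands, cubes = NULL, frequency = NULL,
                            a_mean = NULL, seed = 1L) {
  method <- match.arg(method)
  if (K > n_bands) stopf("K=%d exceeds band count %d", K, n_bands)
  if (method == "random") {
    return(sort(with_seed(seed, sample.int(n_bands, K)) - 1L))
  }
  if (method == "variance") {
    if (is.null(cubes)) stopf("variance method needs training cubes")
    v <- rowMeans(vapply(cubes, function(cb) {
      arr <- if (inherits(cb, "hyper_cube")) cb$values else cb
      apply(matrix(arr, dim(arr)[1]), 1, stats::var)
    }, numeric(n_bands)))
    return(sort(order(v, decreasing = TRUE)[seq_len(K)] - 1L))
  }
  if (is.null(frequency)) stopf("frequency method needs frequency counts")
  finalize_topk(frequency, K, a_mean = a_mean)
}

#' Selection-stability report
#'
#' Summarises how the retained band subset evolves over training: the
#' Jaccard similarity of each epoch's subset to the previous epoch's, the
#' overlap-at-K of each epoch's subset with the final fixed subset, and
#' per-split selection frequencies normalized to a maximum of 1 (with a
#' top-15 table).
#'
#' @param per_epoch_subsets list of 0-based index vectors, one per epoch.
#' @param final_subset 0-based index vector of the fixed subset.
#' @param per_split_frequencies optional named list of per-split frequency
#'   vectors (e.g. train/val/test).
#' @param top_n size of the reported top-frequency table (default 15).
#' @return list of class `stability_report`: `jaccard_prev`, `overlap_k`,
#'   `normalized_frequencies`, `top_table`.
#' @export
stability_report <- function(per_epoch_subsets, final_subset,
                             per_split_frequencies = NULL, top_n = 15L) {
  if (length(per_epoch_subsets) == 0 || length(final_subset) == 0)
    stopf("subsets must be nonempty")
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  ne <- length(per_epoch_subsets)
  jaccard_prev <- c(NA_real_, vapply(seq_len(ne - 1), function(i)
    jac(per_epoch_subsets[[i + 1]], per_epoch_subsets[[i]]), 1))
  K <- length(final_subset)
  overlap_k <- vapply(per_epoch_subsets, function(s)
    length(intersect(s, final_subset)) / K, 1)
  norm_freq <- NULL
  top_table <- NULL
  if (!is.null(per_split_frequencies)) {
    norm_freq <- lapply(per_split_frequencies, function(f)
      if (max(f) > 0) f / max(f) else f)
    top_table <- do.call(rbind, lapply(names(norm_freq), function(nm) {
      f <- norm_freq[[nm]]
      ord <- order(f, decreasing = TRUE)[seq_len(min(top_n, length(f)))]
      data.frame(split = nm, band_index = ord - 1L,
                 normalized_frequency = f[ord], stringsAsFactors = FALSE)
    }))
  }
  structure(list(jaccard_prev = jaccard_prev, overlap_k = overlap_k,
                 normalized_frequencies = norm_freq, top_table = top_table),
            class = "stability_report")
}

#' Per-band spectral entropy
#'
#' Shannon entropy (bits) of the per-band reflectance histogram over
#' `n_hist_bins` equal-width bins on `[0, 1]`, pooled over a collection of
#' cubes.
#'
#' @param cube_collection list of [hyper_cube()]s or band-first arrays with
#'   values in `[0, 1]`.
#' @param n_hist_bins histogram resolution (default 32).
#' @return numeric vector of per-band entropies in bits.
#' @export
band_entropy <- function(cube_collection, n_hist_bins = 32L) {
  if (inherits(cube_collection, "hyper_cube") || is.array(cube_collection))
    cube_collection <- list(cube_collection)
  arrs <- lapply(cube_collection, function(cb)
    if (inherits(cb, "hyper_cube")) cb$values else cb)
  C <- dim(arrs[[1]])[1]
  counts <- matrix(0, C, n_hist_bins)
  for (arr in arrs) {
    m <- matrix(arr, dim(arr)[1])
    bin <- pmin(pmax(floor(m * n_hist_bins) + 1L, 1L), n_hist_bins)
    for (b in seq_len(C))
      counts[b, ] <- counts[b, ] + tabulate(bin[b, ], n_hist_bins)
  }
  apply(counts, 1, function(ct) {
    p <- ct / sum(ct)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}
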