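#' Configuration for the synthetic fruit-phantom generator
#'
#' The phantom generator emulates the structure of VNIR hyperspectral fruit
#' acquisitions: a fruit-shaped region whose reflectance spectrum is a
#' smooth mixture of pigment-, red-edge- and water-related components, a
#' sweetness signal planted on a known set of informative bands whose
#' amplitude is affine in the SSC label, white/dark reference frames, and
#' additive sensor noise. Because the informative bands are known by
#' construction, band selection, reconstruction and regression can all be
#' validated against ground truth.
#'
#' @param n_bands number of spectral bands (default 176).
#' @param height,width spatial dimensions of the generated cubes.
#' @param wavelength_range length-2 numeric, nm span of the band axis
#'   (default `c(404.7, 1010.8)`).
#' @param ssc_range length-2 numeric, admissible SSC label range in degrees
#'   Brix.
#' @param ssc_mean,ssc_sd location and scale of the truncated-normal label
#'   distribution used by [generate_dataset()].
#' @param informative_bands integer vector of 0-based band indices carrying
#'   the SSC signal. Default: four bands in each of the pigment, green,
#'   red-edge and NIR regions.
#' @param noise_sd standard deviation of additive Gaussian noise on raw
#'   intensities (same scale as the references).
#' @param n_samples number of samples produced by [generate_dataset()].
#' @param seed integer seed controlling endmembers and dataset randomness.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_bands = 176L, height = 32L, width = 32L,
                           wavelength_range = c(404.7, 1010.8),
                           ssc_range = c(7, 14), ssc_mean = 10.2,
                           ssc_sd = 1.4, informative_bands = NULL,
                           noise_sd = 0.01, n_samples = 16L, seed = 1L) {
  if (!is_count(n_bands) || n_bands < 8)
    stopf("invalid config: n_bands must be an integer >= 8, got %s", n_bands)
  if (!is_count(height) || !is_count(width))
    stopf("invalid config: height and width must be positive integers")
  if (length(wavelength_range) != 2 || wavelength_range[1] >= wavelength_range[2])
    stopf("invalid config: wavelength_range must be increasing")
  if (length(ssc_range) != 2 || ssc_range[1] >= ssc_range[2])
    stopf("invalid config: ssc_range min must be < max")
  if (noise_sd < 0) stopf("invalid config: noise_sd must be >= 0")
  if (is.null(informative_bands)) {
    anchors <- round(n_bands * c(0.12, 0.33, 0.55, 0.85))
    informative_bands <- sort(unique(as.vector(outer(anchors, 0:3, `+`))))
    informative_bands <- informative_bands[informative_bands < n_bands]
  }
  informative_bands <- sort(unique(as.integer(informative_bands)))
  if (any(informative_bands < 0 | informative_bands >= n_bands))
    stopf("invalid config: informative_bands must lie in [0, n_bands)")
  structure(list(n_bands = as.integer(n_bands), height = as.integer(height),
                 width = as.integer(width),
                 wavelength_range = as.numeric(wavelength_range),
                 ssc_range = as.numeric(ssc_range), ssc_mean = ssc_mean,
                 ssc_sd = ssc_sd, informative_bands = informative_bands,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Smooth spectral endmember curves
#'
#' Builds three nonnegative basis curves on the wavelength grid: a blue
#' pigment-absorption dip, a red-edge sigmoid transition, and an NIR decline
#' toward the water absorption region. Shape parameters are mildly jittered
#' under `seed` so different phantom datasets are not identical.
#'
#' @param n_bands number of bands (>= 8).
#' @param wavelength_range length-2 nm range.
#' @param seed integer seed.
#' @return matrix `n_bands x 3` with columns `pigment`, `red_edge`,
#'   `nir_decline`, all values in `[0, 1]`; attribute `wavelengths` carries
#'   the nm grid.
#' @export
make_endmembers <- function(n_bands, wavelength_range = c(404.7, 1010.8),
                            seed = 1L) {
  if (!is_count(n_bands) || n_bands < 8)
    stopf("invalid config: n_bands must be an integer >= 8, got %s", n_bands)
  wl <- seq(wavelength_range[1], wavelength_range[2], length.out = n_bands)
  jit <- with_seed(seed, stats::rnorm(3, sd = 3))
  pigment <- 1 - 0.85 * exp(-((wl - (460 + jit[1])) / 60)^2)
  red_edge <- sigmoid((wl - (705 + jit[2])) / 22)
  nir_decline <- 1 - 0.75 * sigmoid((wl - (950 + jit[3])) / 25)
  em <- cbind(pigment = pigment, red_edge = red_edge,
              nir_decline = nir_decline)
  em <- pmin(pmax(em, 0), 1)
  attr(em, "wavelengths") <- wl
  em
}

## Deterministic fruit reflectance spectrum for a given label. The
## sweetness component is an absorption term supported exactly on the
## informative bands, with depth affine in the SSC label (sugar-associated
## absorption deepens with SSC). Because the term only lowers reflectance,
## the cube-level value range stays label-independent, and all values stay
## inside (0, 1) without clipping so calibration inverts the forward model
## exactly at zero noise.
phantom_reflectance <- function(config, ssc_value) {
  em <- make_endmembers(config$n_bands, config$wavelength_range, config$seed)
  base <- drop(em %*% c(0.40, 0.35, 0.25))
  ind <- as.numeric((seq_len(config$n_bands) - 1L) %in% config$informative_bands)
  frac <- (ssc_value - config$ssc_range[1]) / diff(config$ssc_range)
  0.25 + 0.55 * base - 0.25 * frac * ind
}

## White/dark reference spectra used for every phantom sample.
phantom_references <- function(config) {
  wl <- seq(config$wavelength_range[1], config$wavelength_range[2],
            length.out = config$n_bands)
  list(white = 0.85 + 0.10 * exp(-((wl - 700) / 250)^2),
       dark = rep(0.04, config$n_bands))
}

#' Generate one synthetic fruit sample
#'
#' Produces a raw-intensity cube plus matching white/dark reference frames.
#' Fruit pixels follow `I = D + R(ssc) * (W - D)` where the reflectance
#' `R(ssc)` carries the planted SSC signal on the configured informative
#' bands; background pixels sit just above the dark level. Additive
#' Gaussian noise (sd `config$noise_sd`) is applied to the raw intensities
#' and the result is clipped to `[dark, white]`.
#'
#' @param config a [phantom_config()].
#' @param ssc_value label in degrees Brix, inside `config$ssc_range`.
#' @param seed integer seed for noise and fruit-shape jitter.
#' @return an object of class `phantom_sample`: list with `cube`
#'   (band-first raw array), `white_ref`, `dark_ref` (same shape),
#'   `ssc_label`, `fruit_mask` (H x W logical), `wavelengths`.
#' @export
generate_sample <- function(config, ssc_value, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (ssc_value < config$ssc_range[1] || ssc_value > config$ssc_range[2])
    stopf("invalid label: ssc_value %.3f outside ssc_range [%g, %g]",
          ssc_value, config$ssc_range[1], config$ssc_range[2])
  C <- config$n_bands; H <- config$height; W <- config$width
  refl <- phantom_reflectance(config, ssc_value)
  refs <- phantom_references(config)
  with_seed(seed, {
    ax <- 0.38 * H * stats::runif(1, 0.9, 1.05)
    ay <- 0.42 * W * stats::runif(1, 0.9, 1.05)
    hh <- (seq_len(H) - (H + 1) / 2) / ax
    ww <- (seq_len(W) - (W + 1) / 2) / ay
    mask <- outer(hh^2, ww^2, `+`) <= 1
    span <- refs$white - refs$dark
    cube <- array(0, c(C, H, W))
    fruit <- refs$dark + refl * span          # length C per fruit pixel
    bg <- refs$dark + 0.01 * span
    for (b in seq_len(C)) {
      plane <- matrix(bg[b], H, W)
      plane[mask] <- fruit[b]
      cube[b, , ] <- plane
    }
    if (config$noise_sd > 0) {
      cube <- cube + stats::rnorm(length(cube), sd = config$noise_sd)
      lo <- array(rep(refs$dark, H * W), c(C, H, W))
      hi <- array(rep(refs$white, H * W), c(C, H, W))
      cube <- pmin(pmax(cube, lo), hi)
    }
    structure(list(
      cube = cube,
      white_ref = array(rep(refs$white, H * W), c(C, H, W)),
      dark_ref = array(rep(refs$dark, H * W), c(C, H, W)),
      ssc_label = ssc_value,
      fruit_mask = mask,
      wavelengths = seq(config$wavelength_range[1], config$wavelength_range[2],
                        length.out = C)), class = "phantom_sample")
  })
}

## Truncated-normal label draws via inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a phantom dataset with a manifest
#'
#' Draws `config$n_samples` SSC labels from a truncated normal over
#' `config$ssc_range` and produces one phantom sample per label. If `dir`
#' is given, cubes and reference frames are written as multi-page TIFF
#' (one page per band) and the manifest is written as `manifest.csv` with
#' columns `id`, `path`, `ssc`.
#'
#' @param config a [phantom_config()].
#' @param dir optional output directory for TIFF cubes and the manifest.
#' @return list with `samples` (list of `phantom_sample`) and `manifest`
#'   (data.frame `id`, `path`, `ssc`).
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_samples
  labels <- with_seed(config$seed,
    rtruncnorm(n, config$ssc_mean, config$ssc_sd,
               config$ssc_range[1], config$ssc_range[2]))
  seeds <- (as.numeric(config$seed) + 7919 * seq_len(n)) %% 2147483647
  samples <- vector("list", n)
  ids <- sprintf("phantom_%04d", seq_len(n))
  paths <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    samples[[i]] <- generate_sample(config, labels[i], seed = seeds[i])
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, paste0(ids[i], ".tif"))
      write_cube(hyper_cube(samples[[i]]$cube,
                            wavelengths = samples[[i]]$wavelengths,
                            provenance = "raw"), p)
      paths[i] <- p
    }
  }
  if (!is.null(dir)) {
    refs <- phantom_references(config)
    write_cube(hyper_cube(array(rep(refs$white, config$height * config$width),
                                c(config$n_bands, config$height, config$width)),
                          provenance = "raw"),
               file.path(dir, "white_ref.tif"))
    write_cube(hyper_cube(array(rep(refs$dark, config$height * config$width),
                                c(config$n_bands, config$height, config$width)),
                          provenance = "raw"),
               file.path(dir, "dark_ref.tif"))
  }
  manifest <- data.frame(id = ids, path = paths, ssc = labels,
                         stringsAsFactors = FALSE)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(samples = samples, manifest = manifest)
}
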