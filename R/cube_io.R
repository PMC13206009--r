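#' Hyperspectral cube container
#'
#' A light container for a band-first reflectance/intensity array with
#' optional wavelength metadata and a provenance flag tracking the
#' preprocessing state.
#'
#' @param values rank-3 numeric array `[band, row, col]`, all finite.
#' @param wavelengths optional length-C strictly increasing nm vector.
#' @param provenance one of `"raw"`, `"calibrated"`, `"normalized"`.
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths = NULL, provenance = "raw") {
  if (!is.array(values) || length(dim(values)) != 3)
    stopf("values must be a rank-3 [band, row, col] array")
  if (!all(is.finite(values))) stopf("cube values must all be finite")
  provenance <- match.arg(provenance, c("raw", "calibrated", "normalized"))
  C <- dim(values)[1]
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != C || any(diff(wavelengths) <= 0))
      stopf("wavelengths must be a strictly increasing length-%d vector", C)
  }
  structure(list(values = values, wavelengths = wavelengths,
                 provenance = provenance), class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d bands x %d x %d (%s)", d[1], d[2], d[3],
              x$provenance))
  if (!is.null(x$wavelengths))
    cat(sprintf(", %.1f-%.1f nm", min(x$wavelengths), max(x$wavelengths)))
  cat("\n")
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Write a cube as a multi-page TIFF (one page per band)
#'
#' @param cube a [hyper_cube()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  pages <- lapply(seq_len(dim(cube$values)[1]),
                  function(b) cube$values[b, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

## Force the spectral axis of a bare array to axis 1, using the expected
## band count to resolve orientation. Used by read_cube and exposed for
## in-memory arrays.
orient_bands_first <- function(values, expected_bands,
                               page_axis_spectral = FALSE) {
  d <- dim(values)
  if (d[1] == expected_bands && d[3] == expected_bands && d[1] != d[3])
    stopf("internal orientation error")                     # unreachable
  if (d[1] == expected_bands && d[3] == expected_bands) {
    warnf("both first and last axis match expected_bands=%d; treating the first as spectral",
          expected_bands)
    return(values)
  }
  if (d[1] == expected_bands) return(values)
  if (d[3] == expected_bands) return(aperm(values, c(3, 1, 2)))
  if (!page_axis_spectral)
    stopf("ambiguous layout: no axis of (%s) matches expected_bands=%d",
          paste(d, collapse = ", "), expected_bands)
  ## Page axis known spectral but of the wrong length: truncate or edge-pad.
  C <- d[1]
  if (C > expected_bands) {
    values[seq_len(expected_bands), , , drop = FALSE]
  } else {
    pad <- values[rep(C, expected_bands - C), , , drop = FALSE]
    arr <- array(0, c(expected_bands, d[2], d[3]))
    arr[seq_len(C), , ] <- values
    arr[(C + 1):expected_bands, , ] <- pad
    arr
  }
}

#' Read a hyperspectral cube from a multi-band TIFF
#'
#' Multi-page files are read one page per band; single-page multi-channel
#' files are treated as band-last and transposed. If the spectral axis does
#' not match `expected_bands` it is truncated or edge-padded (last band
#' replicated) to the target count.
#'
#' @param path TIFF file path.
#' @param expected_bands expected number of spectral bands (>= 1).
#' @param wavelengths optional nm vector attached to the result.
#' @return a raw-provenance [hyper_cube()], band-first.
#' @export
read_cube <- function(path, expected_bands, wavelengths = NULL) {
  if (!file.exists(path)) stopf("cannot read cube: no such file '%s'", path)
  if (!is_count(expected_bands)) stopf("expected_bands must be >= 1")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stopf("I/O error reading '%s': %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) > 1L) {
    if (any(vapply(pages, function(p) length(dim(p)) %||% 2L, 1L) != 2L))
      stopf("ambiguous layout: multi-page file '%s' has non-planar pages", path)
    d2 <- dim(pages[[1]])
    values <- array(unlist(pages, use.names = FALSE),
                    c(d2[1], d2[2], length(pages)))
    values <- aperm(values, c(3, 1, 2))    # page axis is spectral
    values <- orient_bands_first(values, expected_bands,
                                 page_axis_spectral = TRUE)
  } else {
    p <- pages[[1]]
    if (length(dim(p) %||% 2L) == 2L) p <- array(p, c(dim(p), 1L))
    values <- orient_bands_first(p, expected_bands,
                                 page_axis_spectral = FALSE)
  }
  hyper_cube(values, wavelengths = wavelengths, provenance = "raw")
}

#' Reflectance calibration with white/dark references
#'
#' Converts raw intensity to relative reflectance,
#' `R = (I - D) / (W - D)` elementwise, removing dark current and
#' illumination non-uniformity.
#'
#' @param raw a raw [hyper_cube()].
#' @param refs list with `white` and `dark`: arrays matching the cube shape
#'   or length-C per-band vectors (broadcast spatially).
#' @return a calibrated [hyper_cube()].
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "hyper_cube"))
  d <- dim(raw$values)
  expand <- function(x, name) {
    if (is.null(dim(x))) {
      if (length(x) != d[1])
        stopf("%s reference must match band count %d", name, d[1])
      array(rep(x, d[2] * d[3]), d)
    } else {
      if (!all(dim(x) == d))
        stopf("%s reference shape is not broadcastable to the cube", name)
      x
    }
  }
  W <- expand(refs$white, "white")
  D <- expand(refs$dark, "dark")
  denom <- W - D
  if (any(denom <= 0)) {
    bad <- which(apply(denom <= 0, 1, any)) - 1L
    stopf("calibration error: white - dark <= 0 on band(s) %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  hyper_cube((raw$values - D) / denom, wavelengths = raw$wavelengths,
             provenance = "calibrated")
}

#' Percentile clipping and min-max normalization to [0, 1]
#'
#' Clips the cube to its own `[p_lo, p_hi]` voxel percentiles and rescales
#' the clipped range to `[0, 1]`. Percentiles are computed per cube.
#'
#' @param cube a [hyper_cube()].
#' @param p_lo,p_hi lower/upper clipping percentiles (default 1 and 99).
#' @return a normalized [hyper_cube()] with values in `[0, 1]`.
#' @export
percentile_normalize <- function(cube, p_lo = 1, p_hi = 99) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (p_lo >= p_hi) stopf("p_lo must be < p_hi")
  q <- stats::quantile(cube$values, c(p_lo, p_hi) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warnf("degenerate value range (percentiles equal); returning all zeros")
    return(hyper_cube(array(0, dim(cube$values)),
                      wavelengths = cube$wavelengths,
                      provenance = "normalized"))
  }
  v <- pmin(pmax(cube$values, q[1]), q[2])
  hyper_cube((v - q[1]) / (q[2] - q[1]), wavelengths = cube$wavelengths,
             provenance = "normalized")
}

## Mirror-pad a band-first cube spatially so that both spatial dims reach
## at least `size` (edge rows/cols included in the mirror).
reflect_pad_spatial <- function(values, size) {
  mirror_idx <- function(n, target) {
    if (n >= target) return(seq_len(n))
    pad <- target - n
    left <- pad %/% 2
    right <- pad - left
    base <- seq_len(n)
    reflect <- function(k) {
      ## indices continuing past the edges, mirrored with edge included
      i <- ((k - 1) %% (2 * n))
      ifelse(i < n, i + 1, 2 * n - i)
    }
    c(reflect(seq(left, 1)), base, reflect(n + seq_len(right)))
  }
  d <- dim(values)
  ri <- mirror_idx(d[2], size)
  ci <- mirror_idx(d[3], size)
  values[, ri, ci, drop = FALSE]
}

#' Extract a square spatial patch
#'
#' Training mode takes a seeded random crop inside the valid range; eval
#' mode takes the centered crop. Cubes smaller than `size` are mirror-padded
#' spatially first, so extraction never fails.
#'
#' @param cube a [hyper_cube()].
#' @param size patch edge length in pixels (default 448).
#' @param mode `"train"` (random crop) or `"eval"` (center crop).
#' @param seed seed for the random crop in train mode.
#' @return a [hyper_cube()] with spatial dims `size x size`.
#' @export
extract_patch <- function(cube, size = 448L, mode = c("eval", "train"),
                          seed = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  mode <- match.arg(mode)
  if (!is_count(size)) stopf("size must be a positive integer")
  v <- reflect_pad_spatial(cube$values, size)
  d <- dim(v)
  if (mode == "train") {
    off <- with_seed(seed, c(sample.int(d[2] - size + 1L, 1L),
                             sample.int(d[3] - size + 1L, 1L)))
  } else {
    off <- c((d[2] - size) %/% 2L + 1L, (d[3] - size) %/% 2L + 1L)
  }
  hyper_cube(v[, off[1]:(off[1] + size - 1L), off[2]:(off[2] + size - 1L),
               drop = FALSE],
             wavelengths = cube$wavelengths, provenance = cube$provenance)
}

#' Random flip/rotation augmentation
#'
#' Applies horizontal flip, vertical flip and a 90-degree rotation, each
#' independently with probability 0.5 under `seed`. The spectral axis is
#' untouched; every transform permutes pixels within each band.
#'
#' @param patch a [hyper_cube()]; spatial dims must be square when
#'   `rotate = TRUE`.
#' @param seed integer seed.
#' @param rotate include the 90-degree rotation in the transform set.
#' @return the augmented [hyper_cube()].
#' @export
augment <- function(patch, seed = NULL, rotate = TRUE) {
  stopifnot(inherits(patch, "hyper_cube"))
  d <- dim(patch$values)
  if (rotate && d[2] != d[3])
    stopf("config error: rotation requires square spatial dims, got %dx%d",
          d[2], d[3])
  flags <- with_seed(seed, stats::runif(3) < 0.5)
  v <- patch$values
  if (flags[1]) v <- v[, , rev(seq_len(dim(v)[3])), drop = FALSE]   # hflip
  if (flags[2]) v <- v[, rev(seq_len(dim(v)[2])), , drop = FALSE]   # vflip
  if (rotate && flags[3]) v <- rot90_cube(v)
  hyper_cube(v, wavelengths = patch$wavelengths,
             provenance = patch$provenance)
}

## 90-degree counter-clockwise spatial rotation of a band-first cube.
rot90_cube <- function(v) {
  aperm(v, c(1, 3, 2))[, rev(seq_len(dim(v)[3])), , drop = FALSE]
}
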