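#' Band-selection probabilities from importance scores
#'
#' Converts a band-importance vector into a selection distribution through
#' a thresholded, temperature-scaled sigmoid followed by normalization:
#' `p_i = sigma((a_i - tau) / T) / sum_j sigma((a_j - tau) / T)`.
#' Unlike a plain softmax, the threshold `tau` is not cancelled by shift
#' invariance: bands below it are actively suppressed. The temperature `T`
#' controls sharpness (large T explores, small T concentrates).
#'
#' @param a band-importance vector (typically in `(0, 1)`).
#' @param tau threshold.
#' @param T temperature (> 0).
#' @return probability vector summing to 1, order-preserving in `a`.
#' @export
selection_probabilities <- function(a, tau, T) {
  if (T <= 0) stopf("temperature T must be > 0")
  s <- sigmoid((a - tau) / T)
  z <- sum(s)
  if (z < .Machine$double.xmin * length(a) * 10) {
    warnf("all sigmoid terms underflowed; returning uniform probabilities")
    return(rep(1 / length(a), length(a)))
  }
  s / z
}

#' Soft pass-count surrogate
#'
#' Differentiable estimate of how many bands pass the threshold:
#' `K~ = sum_i sigma((a_i - tau) / T_pass)`. Monotone nondecreasing in
#' each `a_i`, decreasing in `tau`, and strictly inside `(0, C)`.
#'
#' @param a band-importance vector.
#' @param tau threshold.
#' @param T_pass counting temperature (> 0).
#' @return scalar soft band count.
#' @export
soft_pass_count <- function(a, tau, T_pass) {
  if (T_pass <= 0) stopf("T_pass must be > 0")
  sum(sigmoid((a - tau) / T_pass))
}

#' Band-budget (compactness) penalty
#'
#' `L_pass = 0.5 * (K~ - K)^2`; zero exactly when the soft count matches
#' the target budget, with gradient `K~ - K` in the soft count.
#'
#' @param K_soft soft pass count.
#' @param K target number of selected bands (>= 1).
#' @return scalar penalty.
#' @export
pass_loss <- function(K_soft, K) {
  if (K < 1) stopf("K must be >= 1")
  0.5 * (K_soft - K)^2
}

#' Soft spectral-spatial gating
#'
#' Applies the spatial attention mask and the per-band soft gate to a cube:
#' `X_soft[i, , ] = X[i, , ] * M_S * sigma((a_i - tau) / T)`. All C
#' channels are retained (gated, not dropped) so downstream shapes stay
#' static and gradients flow into both the mask and the importances.
#'
#' @param cube [hyper_cube()] or band-first array.
#' @param M_S spatial mask, H x W matrix in `(0, 1)`.
#' @param a band-importance vector, length C.
#' @param tau threshold.
#' @param T temperature (> 0).
#' @return list of class `compact_representation`: `values` (gated
#'   band-first array), `gate`, `M_S`, `active` (`NULL` in the soft phase).
#' @export
soft_gate <- function(cube, M_S, a, tau, T) {
  v <- if (inherits(cube, "hyper_cube")) cube$values else cube
  d <- dim(v)
  if (!all(dim(M_S) == d[2:3])) stopf("M_S shape must match cube spatial dims")
  if (length(a) != d[1]) stopf("a must have one entry per band")
  g <- sigmoid((a - tau) / T)
  out <- v * rep(g, d[2] * d[3])            # band-first: g recycles over bands
  mfac <- aperm(array(M_S, c(d[2], d[3], d[1])), c(3, 1, 2))
  out <- out * mfac
  structure(list(values = out, gate = g, M_S = M_S, active = NULL),
            class = "compact_representation")
}

#' Accumulate per-pass selection frequencies
#'
#' One forward pass selects band `i` when `a_i > tau`; the counter for
#' every selected band is incremented. A running mean of `a` is kept for
#' tie-breaking at fixation time.
#'
#' @param state list with `freq` (integer counts), `a_sum`, `a_n`; create
#'   with `selection_state(C)`.
#' @param a band-importance vector.
#' @param tau threshold.
#' @return the updated state.
#' @export
update_frequencies <- function(state, a, tau) {
  sel <- a > tau
  state$freq <- state$freq + as.integer(sel)
  state$a_sum <- state$a_sum + a
  state$a_n <- state$a_n + 1L
  state
}

#' @rdname update_frequencies
#' @param C number of bands.
#' @export
selection_state <- function(C) {
  list(freq = integer(C), a_sum = numeric(C), a_n = 0L)
}

#' Fix the deployable top-K band subset
#'
#' Ranks bands by accumulated selection frequency and returns the K most
#' frequently selected indices. Ties are broken by larger running-mean
#' importance, then by lower band index.
#'
#' @param frequency nonnegative selection counts, length C.
#' @param K number of bands to retain (1 <= K <= C).
#' @param a_mean optional running-mean importance for tie-breaking.
#' @return sorted 0-based integer vector of exactly K distinct indices.
#' @export
finalize_topk <- function(frequency, K, a_mean = NULL) {
  C <- length(frequency)
  if (!is_count(K) || K > C)
    stopf("config error: K must satisfy 1 <= K <= %d", C)
  if (is.null(a_mean)) a_mean <- numeric(C)
  ord <- order(-frequency, -a_mean, seq_len(C))
  sort(ord[seq_len(K)] - 1L)
}

#' Hard band-subset masking
#'
#' Zeroes all non-selected bands while preserving the channel count, and
#' records the active set; this is the deployable compact representation
#' used after top-K fixation.
#'
#' @param cube [hyper_cube()] or band-first array.
#' @param indices 0-based band indices to keep (distinct, within range).
#' @return a `compact_representation` with `active = indices` and a 0/1
#'   `gate`.
#' @export
hard_subset <- function(cube, indices) {
  v <- if (inherits(cube, "hyper_cube")) cube$values else cube
  C <- dim(v)[1]
  indices <- as.integer(indices)
  if (length(indices) < 1) stopf("at least one band must be selected")
  if (anyDuplicated(indices)) stopf("indices must be distinct")
  if (any(indices < 0 | indices >= C))
    stopf("band index out of range [0, %d)", C)
  g <- as.numeric((seq_len(C) - 1L) %in% indices)
  out <- v * rep(g, dim(v)[2] * dim(v)[3])
  structure(list(values = out, gate = g, M_S = NULL,
                 active = sort(indices)),
            class = "compact_representation")
}

#' Export a spatial attention map as a single-band TIFF
#'
#' @param M_S spatial mask matrix in `[0, 1]` (e.g. from
#'   [spatial_attention()]).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_attention_map <- function(M_S, path) {
  tiff::writeTIFF(pmin(pmax(M_S, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Export a selected-band table
#'
#' @param indices 0-based selected band indices.
#' @param n_bands total band count.
#' @param frequency optional per-band selection counts.
#' @param wavelength_range nm range for the index-to-wavelength map.
#' @param path optional CSV output path.
#' @return data.frame with `band_index`, `wavelength_nm`, `frequency`.
#' @export
selected_band_table <- function(indices, n_bands, frequency = NULL,
                                wavelength_range = c(404.7, 1010.8),
                                path = NULL) {
  tab <- data.frame(
    band_index = as.integer(indices),
    wavelength_nm = band_to_wavelength(indices, n_bands, wavelength_range),
    frequency = if (is.null(frequency)) NA_integer_
                else as.integer(frequency[indices + 1L]))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
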