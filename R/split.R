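#' Per-sample summary statistics for the balanced splitter
#'
#' Each sample is characterised by its SSC label, its mean intensity over
#' all voxels, and its mean spectrum (per-band spatial mean).
#'
#' @param cube a calibrated or normalized [hyper_cube()].
#' @param ssc_label SSC label in degrees Brix.
#' @param id sample identifier.
#' @return list of class `sample_summary` with `id`, `ssc_label`,
#'   `mean_intensity`, `mean_spectrum`.
#' @export
summarize_sample <- function(cube, ssc_label, id = NA_character_) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (length(cube$values) == 0) stopf("empty cube")
  C <- dim(cube$values)[1]
  ms <- rowMeans(matrix(cube$values, C))
  structure(list(id = id, ssc_label = ssc_label,
                 mean_intensity = mean(cube$values), mean_spectrum = ms),
            class = "sample_summary")
}

#' Equal-size quantile bins
#'
#' Assigns each value to one of `n_bins` order-preserving bins whose sizes
#' differ by at most one; ties spanning a boundary are resolved by stable
#' input order.
#'
#' @param values numeric vector.
#' @param n_bins number of bins (>= 1).
#' @return integer vector of 0-based bin indices, aligned with `values`.
#' @export
quantile_bins <- function(values, n_bins) {
  if (!is_count(n_bins)) stopf("n_bins must be >= 1")
  n <- length(values)
  ord <- order(values)                       # stable for ties
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(n_bins) - 1L, sizes)
  bins
}

## Jensen-Shannon divergence (natural log) between two count vectors.
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    ok <- a > 0
    sum(a[ok] * log(a[ok] / b[ok]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

## Sufficient statistics of one subset: moments of label and intensity,
## label-bin histogram, spectral sum.
subset_stats <- function(idx, lab, intens, spec, bins, n_bins) {
  list(n = length(idx),
       lab_s1 = sum(lab[idx]), lab_s2 = sum(lab[idx]^2),
       int_s1 = sum(intens[idx]), int_s2 = sum(intens[idx]^2),
       hist = tabulate(bins[idx] + 1L, n_bins),
       spec = if (length(idx) == 1L) spec[idx, ] else colSums(spec[idx, , drop = FALSE]))
}

sd_from_stats <- function(s1, s2, n) {
  if (n < 2) return(0)
  v <- (s2 - s1^2 / n) / (n - 1)
  sqrt(max(v, 0))
}

## Cost from per-subset sufficient statistics; all components standardized
## to be scale-free: moment terms by the global sd of the quantity,
## spectral deviation per band by the across-sample sd of that band.
cost_from_stats <- function(stats_list, glob, weights = c(1, 1, 1)) {
  if (any(vapply(stats_list, function(s) s$n, 1L) == 0L))
    return(list(total = Inf, histogram = Inf, moments = Inf, spectral = Inf))
  pairs <- utils::combn(length(stats_list), 2)
  hist_div <- mean(apply(pairs, 2, function(pr)
    js_divergence(stats_list[[pr[1]]]$hist + 1e-12,
                  stats_list[[pr[2]]]$hist + 1e-12)))
  mom <- 0
  for (s in stats_list) {
    mom <- mom +
      (abs(s$lab_s1 / s$n - glob$lab_mean) +
       abs(sd_from_stats(s$lab_s1, s$lab_s2, s$n) - glob$lab_sd)) /
        max(glob$lab_sd, 1e-12) +
      (abs(s$int_s1 / s$n - glob$int_mean) +
       abs(sd_from_stats(s$int_s1, s$int_s2, s$n) - glob$int_sd)) /
        max(glob$int_sd, 1e-12)
  }
  spc <- 0
  for (s in stats_list) {
    dev <- (s$spec / s$n - glob$spec_mean) / glob$spec_scale
    spc <- spc + sqrt(sum(dev^2) / length(dev))
  }
  comp <- c(histogram = hist_div, moments = mom, spectral = spc)
  total <- sum(weights * comp)
  list(total = total, histogram = comp[[1]], moments = comp[[2]],
       spectral = comp[[3]])
}

split_inputs <- function(summaries, n_bins) {
  lab <- vapply(summaries, function(s) s$ssc_label, 1)
  intens <- vapply(summaries, function(s) s$mean_intensity, 1)
  spec <- do.call(rbind, lapply(summaries, function(s) s$mean_spectrum))
  bins <- quantile_bins(lab, n_bins)
  spec_sd <- apply(spec, 2, stats::sd)
  glob <- list(lab_mean = mean(lab), lab_sd = stats::sd(lab),
               int_mean = mean(intens), int_sd = stats::sd(intens),
               spec_mean = colMeans(spec),
               spec_scale = pmax(spec_sd, 1e-12))
  list(lab = lab, intens = intens, spec = spec, bins = bins, glob = glob)
}

#' Cost of a train/validation/test assignment
#'
#' The total is a weighted sum of three nonnegative components: the mean
#' pairwise Jensen-Shannon divergence of subset label histograms over
#' quantile bins; the sum over subsets of absolute mean and sd deviations
#' from the global values for label and intensity (standardized by the
#' global sd); and the sum over subsets of the per-band-standardized RMS
#' distance between the subset-average spectrum and the global average
#' spectrum. An empty subset has infinite cost.
#'
#' @param assignment character vector over `c("train","val","test")`,
#'   aligned with `summaries`.
#' @param summaries list of [summarize_sample()] results.
#' @param n_bins label-histogram bin count (default 10, capped at n/3).
#' @param weights length-3 component weights (default all 1).
#' @return list with `total`, `histogram`, `moments`, `spectral`.
#' @export
split_cost <- function(assignment, summaries, n_bins = 10L,
                       weights = c(1, 1, 1)) {
  subsets <- c("train", "val", "test")
  if (!all(assignment %in% subsets)) stopf("invalid assignment labels")
  n_bins <- max(1L, min(n_bins, length(summaries) %/% 3L))
  inp <- split_inputs(summaries, n_bins)
  stats_list <- lapply(subsets, function(ss)
    subset_stats(which(assignment == ss), inp$lab, inp$intens, inp$spec,
                 inp$bins, n_bins))
  cost_from_stats(stats_list, inp$glob, weights)
}

## Largest-remainder apportionment of n into parts proportional to ratio.
largest_remainder <- function(n, ratio) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- q - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Distribution-balanced train/validation/test split
#'
#' Samples are stratified into (label-bin x intensity-bin) cells and dealt
#' to subsets at the target ratio; the initial assignment is then refined
#' by first-improvement pairwise cross-subset swaps that are accepted only
#' when the [split_cost()] strictly decreases. Subset sizes are fixed by
#' largest-remainder rounding of the ratio and never change during
#' refinement.
#'
#' @param summaries list of [summarize_sample()] results (>= 3 samples).
#' @param ratio length-3 positive weights, default `c(8, 1, 1)`.
#' @param seed integer seed (cell shuffling and swap proposals).
#' @param max_iter maximum number of swap proposals (default 2000).
#' @param n_bins label-histogram bins for the cost (default 10).
#' @param weights cost component weights.
#' @return object of class `split_assignment`: list with `assignment`
#'   (data.frame `id`, `subset`), `sizes`, `cost` (component list),
#'   `initial_cost`, `cost_trace` (accepted-swap cost sequence).
#' @export
balanced_split <- function(summaries, ratio = c(8, 1, 1), seed = 1L,
                           max_iter = 2000L, n_bins = 10L,
                           weights = c(1, 1, 1)) {
  n <- length(summaries)
  if (n < 3) stopf("need at least 3 samples to split")
  if (length(ratio) != 3 || any(ratio <= 0))
    stopf("config error: ratio must be 3 positive numbers")
  subsets <- c("train", "val", "test")
  n_bins <- max(1L, min(n_bins, n %/% 3L))
  inp <- split_inputs(summaries, n_bins)
  sizes <- largest_remainder(n, ratio)
  if (any(sizes == 0))
    stopf("config error: ratio gives an empty subset for n=%d", n)

  with_seed(seed, {
    ## Stratified initialisation over label x intensity cells.
    lab_bins <- quantile_bins(inp$lab, min(8L, max(1L, n %/% 6L)))
    int_bins <- quantile_bins(inp$intens, min(4L, max(1L, n %/% 12L)))
    cell <- lab_bins * 1000L + int_bins
    ord <- sample.int(n)                     # shuffle, then stable by cell
    ord <- ord[order(cell[ord])]
    assign_idx <- integer(n)
    left <- sizes
    for (i in ord) {
      k <- which.max(left / sizes)
      assign_idx[i] <- k
      left[k] <- left[k] - 1L
    }

    stats_list <- lapply(1:3, function(k)
      subset_stats(which(assign_idx == k), inp$lab, inp$intens, inp$spec,
                   inp$bins, n_bins))
    cur <- cost_from_stats(stats_list, inp$glob, weights)
    initial_cost <- cur
    trace <- cur$total

    move <- function(s, i, sign) {
      s$n <- s$n + sign
      s$lab_s1 <- s$lab_s1 + sign * inp$lab[i]
      s$lab_s2 <- s$lab_s2 + sign * inp$lab[i]^2
      s$int_s1 <- s$int_s1 + sign * inp$intens[i]
      s$int_s2 <- s$int_s2 + sign * inp$intens[i]^2
      b <- inp$bins[i] + 1L
      s$hist[b] <- s$hist[b] + sign
      s$spec <- s$spec + sign * inp$spec[i, ]
      s
    }

    fails <- 0L
    for (it in seq_len(max_iter)) {
      pr <- sample.int(3L, 2L)
      ia <- which(assign_idx == pr[1])
      ib <- which(assign_idx == pr[2])
      i <- ia[sample.int(length(ia), 1L)]
      j <- ib[sample.int(length(ib), 1L)]
      cand <- stats_list
      cand[[pr[1]]] <- move(move(cand[[pr[1]]], i, -1L), j, +1L)
      cand[[pr[2]]] <- move(move(cand[[pr[2]]], j, -1L), i, +1L)
      new <- cost_from_stats(cand, inp$glob, weights)
      if (new$total < cur$total) {
        stats_list <- cand
        assign_idx[c(i, j)] <- c(pr[2], pr[1])
        cur <- new
        trace <- c(trace, cur$total)
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= 500L) break
      }
    }

    ids <- vapply(summaries, function(s) as.character(s$id), "")
    structure(list(
      assignment = data.frame(id = ids, subset = subsets[assign_idx],
                              stringsAsFactors = FALSE),
      sizes = stats::setNames(sizes, subsets),
      cost = cur, initial_cost = initial_cost, cost_trace = trace),
      class = "split_assignment")
  })
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> train/val/test = %s; cost %.4f (hist %.4f, moments %.4f, spectral %.4f)\n",
              paste(x$sizes, collapse = "/"), x$cost$total,
              x$cost$histogram, x$cost$moments, x$cost$spectral))
  invisible(x)
}
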