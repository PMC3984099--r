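# Performance measures: lag-maximised reconstruction accuracy, the combined
# score, the minimum-coefficient rule, bootstrap median comparisons,
# implant-side operation counts and wireless data-rate budgets.

#' Reconstruction accuracy against the true mean waveforms
#'
#' Per spike, the maximum over lags of the normalised cross-correlation
#' between the (reconstructed) spike and the noiseless template of its
#' neuron of origin; the mean over spikes is returned. Normalisation uses
#' the Euclidean norms of the overlapping segments at each lag, so a purely
#' lag-shifted noiseless template scores 1. The lag search is restricted to
#' `max_lag` samples either way, which covers alignment residuals while
#' preventing spurious matches at near-zero overlap.
#'
#' @param Xhat M x N matrix (or `spike_matrix`) of reconstructed spikes.
#' @param templates list (indexed by neuron id) of M-sample noiseless
#'   templates, or a M x n_neurons matrix.
#' @param true_ids neuron id of each spike.
#' @param max_lag lag search radius, samples.
#' @return mean reconstruction accuracy in `[-1, 1]` (in practice `[0, 1]`),
#'   with per-spike values as attribute `"per_spike"`.
#' @export
reconstruction_accuracy <- function(Xhat, templates, true_ids, max_lag = 10) {
  Xm <- spike_waveform_matrix(Xhat)
  M <- nrow(Xm)
  n <- ncol(Xm)
  if (length(true_ids) != n) stop("true_ids must match the number of spikes")
  if (is.matrix(templates))
    templates <- lapply(seq_len(ncol(templates)), function(j) templates[, j])
  acc <- numeric(n)
  lags <- -max_lag:max_lag
  for (id in unique(true_ids)) {
    tmpl <- templates[[id]]
    cols <- which(true_ids == id)
    Xi <- Xm[, cols, drop = FALSE]
    if (sqrt(sum(tmpl^2)) == 0) {
      warning("zero-energy template; affected spikes scored 0")
      next
    }
    best <- rep(-Inf, length(cols))
    for (lag in lags) {
      if (lag >= 0) { ta <- 1 + lag; tb <- M; xa <- 1; xb <- M - lag }
      else { ta <- 1; tb <- M + lag; xa <- 1 - lag; xb <- M }
      tseg <- tmpl[ta:tb]
      Xseg <- Xi[xa:xb, , drop = FALSE]
      tn <- sqrt(sum(tseg^2))
      xn <- sqrt(colSums(Xseg^2))
      num <- as.numeric(crossprod(tseg, Xseg))
      r <- ifelse(tn * xn > 0, num / (tn * xn), -Inf)
      best <- pmax(best, r)
    }
    zero <- !is.finite(best)
    if (any(zero)) {
      warning("zero-energy spike(s) scored 0")
      best[zero] <- 0
    }
    acc[cols] <- best
  }
  out <- mean(acc)
  attr(out, "per_spike") <- acc
  out
}

#' Combined reconstruction/sorting score
#'
#' Arithmetic mean of the reconstruction and sorting accuracies; both lie in
#' `[0, 1]`, so the score does too.
#'
#' @param A_rec mean reconstruction accuracy in `[0, 1]`.
#' @param A_sort sorting accuracy in `[0, 1]`.
#' @return score in `[0, 1]`.
#' @export
combined_score <- function(A_rec, A_sort) {
  if (any(A_rec < 0 | A_rec > 1) || any(A_sort < 0 | A_sort > 1))
    stop("accuracies must lie in [0, 1]")
  (A_rec + A_sort) / 2
}

#' Effective minimum number of compression coefficients
#'
#' Scores measured on a coarse grid of coefficient counts are interpolated
#' with a cubic spline onto the integer grid spanning the evaluated points;
#' the result is the smallest integer L whose interpolated score is at most
#' 0.01 below the maximum interpolated score.
#'
#' @param L evaluated coefficient counts (>= 3 distinct values).
#' @param score scores at those counts; alternatively pass a named numeric
#'   vector as `L` (names = counts) and omit `score`.
#' @param tolerance allowed shortfall from the maximum score.
#' @return integer minimum coefficient count.
#' @export
min_coefficients <- function(L, score = NULL, tolerance = 0.01) {
  if (is.null(score)) {
    score <- as.numeric(L)
    L <- as.numeric(names(L))
  }
  if (length(L) < 3) stop("need at least 3 evaluated coefficient counts")
  o <- order(L)
  L <- L[o]; score <- score[o]
  grid <- seq(ceiling(min(L)), floor(max(L)))
  sp <- stats::spline(L, score, xout = grid)
  ok <- sp$y >= max(sp$y) - tolerance
  as.integer(grid[which(ok)[1]])
}

#' Bootstrap comparison of two group medians
#'
#' Percentile-bootstrap confidence intervals for the median of each group;
#' the difference is called significant when the intervals are disjoint.
#'
#' @param groupA,groupB numeric vectors, each with at least 5 values.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level of each interval.
#' @return list with `significant` (logical), `ci_a`, `ci_b`, `median_a`,
#'   `median_b`.
#' @export
median_compare <- function(groupA, groupB, n_boot = 2000, seed = 1L,
                           conf = 0.95) {
  if (length(groupA) < 5 || length(groupB) < 5)
    stop("each group needs at least 5 values")
  set.seed(seed)
  boot_ci <- function(x) {
    meds <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(x, replace = TRUE)), numeric(1))
    stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }
  ca <- boot_ci(groupA)
  cb <- boot_ci(groupB)
  list(significant = (ca[2] < cb[1]) || (cb[2] < ca[1]),
       ci_a = ca, ci_b = cb,
       median_a = stats::median(groupA), median_b = stats::median(groupB))
}

#' Implant-side operation cost model
#'
#' One operation is a one-bit addition. Adding two words costs
#' `word_length` operations; subtraction and comparison cost the same as
#' addition; multiplication and division cost `mult_factor` times as much.
#'
#' @param word_length sample word length, bits.
#' @param mult_factor multiplication cost relative to addition.
#' @param fs sampling rate, Hz.
#' @param spikes_per_second spike rate used to attribute per-spike stages
#'   (default 40 = 4 neurons x 10 spikes/s).
#' @return an object of class `cost_model`.
#' @export
cost_model <- function(word_length = 10, mult_factor = 10, fs = 25000,
                       spikes_per_second = 40) {
  if (word_length < 0 || mult_factor < 0) stop("costs must be non-negative")
  structure(list(word_length = word_length,
                 add_cost = word_length,
                 mult_cost = mult_factor * word_length,
                 fs = fs,
                 spikes_per_second = spikes_per_second),
            class = "cost_model")
}

#' Implant-side operation count of a configuration
#'
#' Counts the operations executed on the implant: the detection statistic
#' runs on every sample (ABS: one comparison; NEO: two multiplications, one
#' subtraction and one comparison), implant-side alignment (architecture 3)
#' costs one comparison per searched sample per spike, and compression costs
#' one M-point multiply-accumulate (M multiplications, M - 1 additions) per
#' transmitted coefficient per spike. Continuous stages are counted per
#' second of signal; per-spike stages are attributed with the model's spike
#' rate; the compression term is quoted per coefficient (per dimension),
#' which is the convention under which the total is reported as
#' "MOPS per spike per dimension".
#'
#' @param architecture 0, 1, 2 or 3.
#' @param detector `"ABS"` or `"NEO"`.
#' @param L transmitted coefficients (unused by architecture 0).
#' @param model a [cost_model].
#' @param M spike window length, samples.
#' @param align_window implant alignment search length, samples.
#' @return list with `mops` (total million operations per second under the
#'   attribution convention above) and the `detection`, `alignment`,
#'   `compression` components (ops/s).
#' @export
op_count <- function(architecture, detector = c("ABS", "NEO"), L = 4,
                     model = cost_model(), M = 64, align_window = 13) {
  detector <- match.arg(detector)
  if (!architecture %in% 0:3) stop("unknown architecture")
  det_per_sample <- if (detector == "ABS") model$add_cost
                    else 2 * model$mult_cost + 2 * model$add_cost
  detection <- det_per_sample * model$fs
  alignment <- if (architecture == 3)
    align_window * model$add_cost * model$spikes_per_second else 0
  compression <- if (architecture %in% 1:3)
    (M * model$mult_cost + (M - 1) * model$add_cost) * model$spikes_per_second
  else 0
  total <- detection + alignment + compression
  list(mops = total / 1e6,
       detection = detection, alignment = alignment,
       compression = compression)
}

#' Wireless data-rate budget
#'
#' Closed-form data-rate accounting for spike-waveform transmission:
#' bits per compressed spike, compression factor relative to the full
#' 64-sample waveform, mean per-channel rate for a given neuron count and
#' firing rate, reduction relative to streaming the raw samples, and the
#' number of channels a given link capacity supports.
#'
#' @param L transmitted compression coefficients per spike.
#' @param bits_per_sample quantisation word length, bits.
#' @param samples_per_spike uncompressed spike length, samples.
#' @param neurons_per_channel mean neurons per recording channel.
#' @param rate_per_neuron mean firing rate per neuron, spikes/s.
#' @param link_capacity wireless link capacity, bits/s.
#' @param fs raw sampling rate, Hz.
#' @return an object of class `data_rate`: `bits_per_spike`,
#'   `raw_bits_per_spike`, `compression_factor`, `channel_rate`,
#'   `raw_channel_rate` (bits/s), `reduction` (fraction),
#'   `channels_supported`, `raw_channels_supported`, `channel_gain_factor`.
#' @export
data_rate <- function(L = 4, bits_per_sample = 10, samples_per_spike = 64,
                      neurons_per_channel = 4, rate_per_neuron = 10,
                      link_capacity = 1e6, fs = 25000) {
  if (any(c(L, bits_per_sample, samples_per_spike, neurons_per_channel,
            rate_per_neuron, link_capacity, fs) <= 0))
    stop("all arguments must be positive")
  bits_per_spike <- L * bits_per_sample
  raw_bits_per_spike <- samples_per_spike * bits_per_sample
  channel_rate <- neurons_per_channel * rate_per_neuron * bits_per_spike
  raw_channel_rate <- fs * bits_per_sample
  channels <- floor(link_capacity / channel_rate)
  raw_channels <- floor(link_capacity / raw_channel_rate)
  structure(list(
    bits_per_spike = bits_per_spike,
    raw_bits_per_spike = raw_bits_per_spike,
    compression_factor = raw_bits_per_spike / bits_per_spike,
    channel_rate = channel_rate,
    raw_channel_rate = raw_channel_rate,
    reduction = 1 - channel_rate / raw_channel_rate,
    channels_supported = channels,
    raw_channels_supported = raw_channels,
    channel_gain_factor = channels / raw_channels
  ), class = "data_rate")
}

#' @export
print.data_rate <- function(x, ...) {
  cat(sprintf("<data_rate> %g bits/spike (raw %g), compression factor %g\n",
              x$bits_per_spike, x$raw_bits_per_spike, x$compression_factor))
  cat(sprintf("  channel %g bits/s vs raw %g bits/s (%.2f%% reduction)\n",
              x$channel_rate, x$raw_channel_rate, 100 * x$reduction))
  cat(sprintf("  link supports %d channels (raw: %d; factor %g)\n",
              x$channels_supported, x$raw_channels_supported,
              x$channel_gain_factor))
  invisible(x)
}
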