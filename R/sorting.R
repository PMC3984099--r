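# Spike sorting at the external unit: PCA features, K-means clustering and
# permutation-matched sorting accuracy.

#' First principal-component features of spike waveforms
#'
#' Mean-centred projection of the spikes onto the top principal components
#' of the (reconstructed) waveform matrix, components ordered by explained
#' variance, signs fixed so the largest-magnitude loading of every component
#' is positive.
#'
#' @param X M x N matrix of spike waveforms in columns (or `spike_matrix`).
#' @param n_components number of features per spike.
#' @return N x `n_components` feature matrix, with the component loadings as
#'   attribute `"rotation"`.
#' @export
pca_features <- function(X, n_components = 3) {
  Xm <- spike_waveform_matrix(X)
  n <- ncol(Xm)
  if (n < n_components) stop("need at least n_components spikes")
  p <- stats::prcomp(t(Xm), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  feats <- p$x[, seq_len(k), drop = FALSE]
  feats <- sweep(feats, 2, flip, `*`)
  if (k < n_components)
    feats <- cbind(feats, matrix(0, n, n_components - k))
  attr(feats, "rotation") <- rot
  feats
}

#' Cluster spike features with K-means
#'
#' Best-of-restarts K-means with the true number of clusters supplied; the
#' run with the lowest within-cluster sum of squares wins.
#'
#' @param features N x d feature matrix.
#' @param K number of clusters.
#' @param seed RNG seed.
#' @param restarts number of random restarts.
#' @param iter_max maximum iterations per run.
#' @return integer cluster labels of length N.
#' @export
kmeans_cluster <- function(features, K = 4, seed = 1L, restarts = 10,
                           iter_max = 300) {
  features <- as.matrix(features)
  if (K > nrow(features)) stop("K exceeds the number of spikes")
  set.seed(seed)
  ux <- unique(features)
  if (nrow(ux) < K) stop("fewer distinct feature points than clusters")
  if (nrow(ux) == K) {
    km <- stats::kmeans(features, centers = ux, iter.max = iter_max)
    return(km$cluster)
  }
  km <- NULL
  for (attempt in seq_len(50)) {
    km <- tryCatch(
      stats::kmeans(features, centers = K, nstart = restarts,
                    iter.max = iter_max),
      error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("K-means failed to produce a clustering")
  km$cluster
}

# All permutations of a vector (small n only).
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

#' Sorting accuracy under the best cluster-to-neuron matching
#'
#' The fraction of spikes whose cluster label matches their true neuron
#' identity, maximised over all injective mappings between cluster labels
#' and neuron labels (exhaustive search; exact for up to 6 labels on the
#' smaller side).
#'
#' @param assigned cluster labels.
#' @param true_ids ground-truth neuron labels of the same length.
#' @return accuracy in `[0, 1]`.
#' @export
sorting_accuracy <- function(assigned, true_ids) {
  if (length(assigned) != length(true_ids))
    stop("assigned and true_ids must have equal length")
  n <- length(assigned)
  if (n == 0) stop("empty label vectors")
  cl <- sort(unique(assigned))
  tl <- sort(unique(true_ids))
  # contingency table: rows clusters, cols true classes
  tab <- table(factor(assigned, levels = cl), factor(true_ids, levels = tl))
  small_on_rows <- length(cl) <= length(tl)
  if (small_on_rows) {
    ns <- length(cl); nl <- length(tl); m <- tab
  } else {
    ns <- length(tl); nl <- length(cl); m <- t(tab)
  }
  if (ns > 6 || nl > 7)
    stop("exhaustive matching supports at most 6-7 labels")
  best <- 0
  for (p in all_perms(seq_len(nl))) {
    sel <- p[seq_len(ns)]
    hit <- sum(m[cbind(seq_len(ns), sel)])
    if (hit > best) best <- hit
  }
  best / n
}
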