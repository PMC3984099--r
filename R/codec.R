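# Transform coding of spike waveforms: A = W'X, C = E A, X_hat = W E' C.
# Five bases: the recording-optimal SVD basis, two fixed SVD bases (one from
# a model-derived library, one from the packaged generic surrogate library),
# plain downsampling, and the orthonormal Haar wavelet basis.

# Fix the arbitrary SVD column signs: the largest-magnitude element of every
# column is made positive, so frozen fixtures are stable across LAPACK builds.
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

new_basis <- function(W, kind, singular_values = NULL,
                      interpolation_required = FALSE, D = NULL) {
  structure(list(W = W, kind = kind, singular_values = singular_values,
                 interpolation_required = interpolation_required, D = D),
            class = "compression_basis")
}

#' @export
print.compression_basis <- function(x, ...) {
  cat(sprintf("<compression_basis> kind '%s', M = %d%s\n", x$kind,
              nrow(x$W),
              if (x$interpolation_required) " (interpolating)" else ""))
  invisible(x)
}

spike_waveform_matrix <- function(X) {
  if (inherits(X, "spike_matrix")) X$waveforms else as.matrix(X)
}

#' Recording-optimal SVD compression basis
#'
#' Left singular vectors of the spike-waveform matrix, ordered by descending
#' singular value. This is the reference basis: it is derived from the very
#' spikes being compressed, so by the Eckart-Young theorem truncating to the
#' first L coefficients is optimal in the Frobenius sense.
#'
#' @param X a `spike_matrix` or M x N numeric matrix of spike waveforms in
#'   columns.
#' @return a `compression_basis` of kind `"optimal"` with the singular
#'   values stored.
#' @export
build_optimal_basis <- function(X) {
  Xm <- spike_waveform_matrix(X)
  if (ncol(Xm) < 1) stop("spike matrix is empty")
  M <- nrow(Xm)
  sv <- svd(Xm, nu = M, nv = 0)
  d <- c(sv$d, numeric(M))[1:M]
  new_basis(fix_signs(sv$u), "optimal", singular_values = d)
}

#' Fixed SVD compression basis from a waveform library
#'
#' Same construction as the optimal basis, but applied to an independent
#' spike-waveform library so the basis never has to be recomputed on the
#' implant. Kind `"fixed1"` denotes the model-derived library
#' ([make_model_point_library]); kind `"fixed2"` the generic surrogate
#' library ([make_surrogate_library]), which is unrelated to the test data.
#'
#' @param library M x K matrix of library waveforms in columns, K >= M.
#' @param kind `"fixed1"` or `"fixed2"`.
#' @return a `compression_basis`.
#' @export
build_fixed_basis <- function(library, kind = c("fixed1", "fixed2")) {
  kind <- match.arg(kind)
  library <- as.matrix(library)
  M <- nrow(library)
  if (ncol(library) < M)
    stop("library must contain at least as many waveforms as samples per waveform")
  sv <- svd(library, nu = M, nv = 0)
  d <- c(sv$d, numeric(M))[1:M]
  b <- new_basis(fix_signs(sv$u), kind, singular_values = d)
  b
}

#' Downsampling compression basis
#'
#' The basis matrix is the identity; compression keeps every D-th sample,
#' where `D = round(M / L)`, starting at the first. No antialiasing filter
#' is applied before discarding samples. Reconstruction inserts zeros and
#' applies an ideal frequency-domain lowpass interpolation filter with
#' cutoff `fs / (2 D)`.
#'
#' @param M waveform length, samples.
#' @param L nominal number of kept coefficients, 1 <= L <= M. The number of
#'   samples actually kept is `ceiling(M / D)` and may differ slightly from
#'   L when D does not divide M.
#' @return a `compression_basis` of kind `"downsample"`.
#' @export
build_downsampling_basis <- function(M, L) {
  if (L < 1 || L > M) stop("L must lie in [1, M]")
  D <- max(1L, as.integer(round(M / L)))
  new_basis(diag(M), "downsample", interpolation_required = TRUE, D = D)
}

#' Orthonormal Haar wavelet compression basis
#'
#' Canonical scale-major (coarse-first) orthonormal Haar matrix; the
#' columns of W hold the discrete-time Haar basis waveforms, so the first
#' coefficient is the scaling (mean) coefficient. Dimensionality reduction
#' keeps the first L coefficients without any per-spike optimisation.
#'
#' @param M waveform length; must be a power of two.
#' @return a `compression_basis` of kind `"haar"`.
#' @export
build_haar_basis <- function(M) {
  if (M < 1 || bitwAnd(M, M - 1L) != 0)
    stop("M must be a power of two")
  H <- matrix(1, 1, 1)
  while (nrow(H) < M) {
    n <- nrow(H)
    H <- rbind(kronecker(H, t(c(1, 1))),
               kronecker(diag(n), t(c(1, -1))))
  }
  H <- H / sqrt(rowSums(H^2))
  new_basis(t(H), "haar")
}

# Rows of the full transform kept for a given basis kind and L.
selected_rows <- function(basis, L, M) {
  if (L < 1 || L > M) stop("L must lie in [1, M]")
  if (basis$kind == "downsample") {
    D <- max(1L, as.integer(round(M / L)))
    seq(1L, M, by = D)
  } else {
    seq_len(L)
  }
}

#' Compress spike waveforms to L transform coefficients
#'
#' Computes the full transform `A = W' X` and keeps the rows selected by the
#' dimensionality-reduction matrix of the basis kind: the first L rows for
#' the SVD and Haar bases, every D-th row for downsampling.
#'
#' @param X a `spike_matrix` or M x N matrix.
#' @param basis a `compression_basis` with matching M.
#' @param L number of compression coefficients.
#' @return an object of class `coefficient_set` with fields `C` (L_eff x N),
#'   `rows` (kept transform rows), `L` (effective kept count), `kind`, `M`,
#'   `bits_per_coeff`, `quantized`.
#' @export
compress <- function(X, basis, L) {
  Xm <- spike_waveform_matrix(X)
  M <- nrow(Xm)
  if (nrow(basis$W) != M) stop("basis dimension does not match the spike matrix")
  rows <- selected_rows(basis, L, M)
  A <- crossprod(basis$W, Xm)
  structure(list(C = A[rows, , drop = FALSE], rows = rows,
                 L = length(rows), kind = basis$kind, M = M,
                 bits_per_coeff = 10L, quantized = FALSE),
            class = "coefficient_set")
}

#' Uniformly quantize compression coefficients
#'
#' Mid-rise uniform quantization over the observed coefficient range, used
#' only to make the data-rate accounting realistic; off by default in the
#' processing chains.
#'
#' @param coeffs a `coefficient_set`.
#' @param bits word length in bits (>= 2).
#' @return the quantized `coefficient_set`.
#' @export
quantize_coefficients <- function(coeffs, bits = 10) {
  if (bits < 2) stop("bits must be at least 2")
  C <- coeffs$C
  lo <- min(C); hi <- max(C)
  if (hi <= lo) {
    warning("degenerate coefficient range; returning coefficients unchanged")
    coeffs$quantized <- TRUE
    coeffs$bits_per_coeff <- as.integer(bits)
    return(coeffs)
  }
  step <- (hi - lo) / 2^bits
  q <- lo + (floor((C - lo) / step) + 0.5) * step
  q[C == hi] <- hi - step / 2
  coeffs$C <- q
  coeffs$quantized <- TRUE
  coeffs$bits_per_coeff <- as.integer(bits)
  coeffs
}

# Ideal frequency-domain lowpass interpolation: zero-stuffed columns are
# filtered at cutoff fs/(2D) and scaled by D to restore the passband gain.
lowpass_interpolate <- function(x, D) {
  N <- length(x)
  X <- stats::fft(x)
  k <- 0:(N - 1)
  k[k > N / 2] <- k[k > N / 2] - N
  keep <- abs(k) < N / (2 * D)
  X[!keep] <- 0
  Re(stats::fft(X * D, inverse = TRUE)) / N
}

#' Reconstruct spike waveforms from compression coefficients
#'
#' `X_hat = W E' C`; for the downsampling basis the zero-stuffed
#' reconstruction is additionally passed through the ideal lowpass
#' interpolation filter.
#'
#' @param coeffs a `coefficient_set`.
#' @param basis the `compression_basis` the coefficients were computed with.
#' @return M x N matrix of reconstructed waveforms.
#' @export
reconstruct <- function(coeffs, basis) {
  M <- nrow(basis$W)
  if (coeffs$M != M || coeffs$kind != basis$kind)
    stop("coefficients and basis are inconsistent")
  Xhat <- basis$W[, coeffs$rows, drop = FALSE] %*% coeffs$C
  if (isTRUE(basis$interpolation_required)) {
    D <- if (length(coeffs$rows) >= 2) coeffs$rows[2] - coeffs$rows[1] else M
    if (D > 1L) Xhat <- apply(Xhat, 2, lowpass_interpolate, D = D)
    if (!is.matrix(Xhat)) Xhat <- matrix(Xhat, nrow = M)
  }
  Xhat
}
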