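# Band-limited resampling primitives shared by the jitter-emulation and
# alignment stages. All interpolation is Fourier (zero-padding the spectrum),
# so values at the original sample instants are preserved exactly.

#' Upsample a vector by an integer factor with Fourier interpolation
#'
#' Zero-pads the discrete spectrum, which is the band-limited interpolation
#' used when waveforms sampled at 25 kHz are taken to a 200 kHz grid for
#' threshold-crossing timing and sub-sample alignment.
#'
#' @param x numeric vector.
#' @param p integer upsampling factor (>= 1).
#' @return numeric vector of length `length(x) * p`; `x` is recovered exactly
#'   at positions `seq(1, length(x) * p, by = p)`.
#' @export
fft_upsample <- function(x, p) {
  p <- as.integer(p)
  stopifnot(p >= 1, length(x) >= 2)
  if (p == 1L) return(as.numeric(x))
  n <- length(x)
  np <- n * p
  X <- stats::fft(x)
  Xp <- complex(length.out = np)
  half <- n %/% 2L
  if (n %% 2L == 0L) {
    # split the Nyquist bin so the interpolant stays real and symmetric
    Xp[1:half] <- X[1:half]
    Xp[half + 1L] <- X[half + 1L] / 2
    Xp[np - half + 1L] <- Conj(X[half + 1L]) / 2
    if (half > 1L) Xp[(np - half + 2L):np] <- X[(half + 2L):n]
  } else {
    Xp[1:(half + 1L)] <- X[1:(half + 1L)]
    Xp[(np - half + 1L):np] <- X[(half + 2L):n]
  }
  Re(stats::fft(Xp, inverse = TRUE)) * p / np
}

#' Decimate a vector by an integer factor
#'
#' Keeps every `p`-th sample starting at the first. No antialiasing filter is
#' applied; callers that need one apply it beforehand.
#'
#' @param x numeric vector.
#' @param p integer decimation factor.
#' @return numeric vector of the retained samples.
#' @export
fft_decimate <- function(x, p) {
  p <- as.integer(p)
  stopifnot(p >= 1)
  x[seq(1L, length(x), by = p)]
}

# Integer shift with zero fill: positive d moves content later in time.
shift_int <- function(x, d) {
  n <- length(x)
  d <- as.integer(round(d))
  if (d == 0L) return(x)
  out <- numeric(n)
  if (d > 0L) {
    if (d < n) out[(d + 1L):n] <- x[1:(n - d)]
  } else {
    if (-d < n) out[1:(n + d)] <- x[(1L - d):n]
  }
  out
}
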