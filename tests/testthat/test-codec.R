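# Transform coding: basis construction, compression, quantization and
# reconstruction.

test_that("optimal basis is the SVD of the spike matrix", {
  set.seed(10)
  v <- stats::rnorm(64)
  X <- matrix(rep(v, 5), 64, 5)
  b <- build_optimal_basis(X)
  expect_equal(abs(as.numeric(crossprod(b$W[, 1], v / sqrt(sum(v^2))))), 1,
               tolerance = 1e-10)
  # sign convention: largest-magnitude element positive
  expect_true(all(apply(b$W, 2, function(c) c[which.max(abs(c))]) > 0))
  X2 <- matrix(stats::rnorm(64 * 100), 64)
  b2 <- build_optimal_basis(X2)
  expect_equal(crossprod(b2$W), diag(64), tolerance = 1e-10)
  expect_true(all(diff(b2$singular_values) <= 1e-12))
  expect_error(build_optimal_basis(matrix(numeric(0), 64, 0)), "empty")
})

test_that("optimal-basis reconstruction error equals the singular tail sum", {
  set.seed(11)
  X <- matrix(stats::rnorm(64 * 200), 64)
  b <- build_optimal_basis(X)
  s2 <- b$singular_values^2
  for (L in c(1, 2, 4, 8, 16, 32, 63, 64)) {
    Xhat <- reconstruct(compress(X, b, L), b)
    err <- sum((X - Xhat)^2)
    tail <- sum(s2[seq_len(64) > L])
    if (tail == 0) expect_lt(err, 1e-16)
    else expect_equal(err, tail, tolerance = 1e-8)
  }
})

test_that("reconstruction error is monotone non-increasing in L for SVD bases", {
  set.seed(12)
  X <- matrix(stats::rnorm(64 * 80), 64)
  for (b in list(build_optimal_basis(X), fixed2_basis())) {
    errs <- vapply(1:64, function(L)
      sum((X - reconstruct(compress(X, b, L), b))^2), numeric(1))
    expect_true(all(diff(errs) <= 1e-8))
  }
})

test_that("fixed bases are library-derived and close to optimal at L = 8", {
  lib <- make_model_point_library(n_per_neuron = 200, seed = 4)
  b1 <- build_fixed_basis(lib, "fixed1")
  expect_identical(b1$W, build_fixed_basis(lib, "fixed1")$W)
  expect_error(build_fixed_basis(matrix(1, 64, 10), "fixed1"), "at least")

  sm <- align_spikes(test_spikes(), alignment_config("implant"))
  bopt <- build_optimal_basis(sm)
  rec <- test_recording()
  tmpl <- lapply(rec$templates, function(t) t[1, ])
  acc <- function(b) as.numeric(reconstruction_accuracy(
    reconstruct(compress(sm, b, 8), b), tmpl, sm$true_ids))
  expect_lt(abs(acc(fixed1_basis()) - acc(bopt)), 0.03)
})

test_that("downsampling keeps every D-th sample and interpolates back", {
  b <- build_downsampling_basis(64, 16)
  co <- compress(matrix(stats::rnorm(64 * 3), 64), b, 16)
  expect_identical(co$rows, seq(1L, 61L, by = 4L))
  expect_identical(co$L, 16L)
  b64 <- build_downsampling_basis(64, 64)
  co64 <- compress(diag(64), b64, 64)
  expect_identical(co64$rows, 1:64)
  # DC vector is recovered exactly
  dc <- matrix(1, 64, 1)
  out <- reconstruct(compress(dc, b, 16), b)
  expect_equal(as.numeric(out), rep(1, 64), tolerance = 1e-10)
  # band-limited content below fs/(2D) is recovered exactly (Nyquist)
  k <- 3 # cycles across the window; bin 3 < 64/(2*4) = 8
  x <- matrix(cos(2 * pi * k * (0:63) / 64), 64, 1)
  out2 <- reconstruct(compress(x, b, 16), b)
  expect_equal(as.numeric(out2), as.numeric(x), tolerance = 1e-6)
  expect_error(build_downsampling_basis(64, 65), "L must lie")
})

test_that("Haar basis is the orthonormal scale-major wavelet matrix", {
  b2 <- build_haar_basis(2)
  expect_equal(b2$W, cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2)))
  b <- build_haar_basis(64)
  expect_equal(crossprod(b$W), diag(64), tolerance = 1e-12)
  # constant vector: all energy in the scaling coefficient
  co <- compress(matrix(1, 64, 1), b, 64)
  expect_equal(co$C[1, 1], 8)
  expect_equal(sum(co$C[-1, 1]^2), 0, tolerance = 1e-20)
  expect_error(build_haar_basis(48), "power of two")
})

test_that("orthonormal transforms preserve energy and invert at L = M", {
  set.seed(13)
  X <- matrix(stats::rnorm(64 * 30), 64)
  for (b in list(build_optimal_basis(X), build_haar_basis(64), fixed2_basis())) {
    co <- compress(X, b, 64)
    expect_equal(sqrt(sum(co$C^2)), sqrt(sum(X^2)), tolerance = 1e-10)
    expect_equal(reconstruct(co, b), X, tolerance = 1e-10)
  }
  # X = first basis column at L = 1: a single nonzero coefficient
  b <- build_haar_basis(64)
  co1 <- compress(3.2 * b$W[, 1, drop = FALSE], b, 1)
  expect_equal(as.numeric(co1$C), 3.2, tolerance = 1e-12)
})

test_that("truncated orthonormal coding equals orthogonal projection", {
  set.seed(14)
  X <- matrix(stats::rnorm(16 * 10), 16)
  b <- build_optimal_basis(X)
  L <- 5
  P <- b$W[, 1:L] %*% t(b$W[, 1:L])   # explicit projector
  expect_equal(reconstruct(compress(X, b, L), b), P %*% X, tolerance = 1e-10)
})

test_that("SVD coefficient energy concentrates in the leading rows", {
  set.seed(15)
  # low-rank-ish small instance; brute-force over all 4-subsets of 8 rows
  base <- matrix(stats::rnorm(8 * 3), 8)
  X <- base %*% matrix(stats::rnorm(3 * 20), 3) +
    0.1 * matrix(stats::rnorm(8 * 20), 8)
  b <- build_optimal_basis(X)
  A <- crossprod(b$W, X)
  energy <- rowSums(A^2)
  lead <- sum(energy[1:4])
  subsets <- utils::combn(8, 4)
  best_other <- max(apply(subsets, 2, function(s) sum(energy[s])))
  expect_gte(lead + 1e-12, best_other)
})

test_that("quantization error is bounded by the step size", {
  set.seed(16)
  X <- matrix(stats::rnorm(64 * 20), 64)
  b <- build_haar_basis(64)
  co <- compress(X, b, 64)
  q24 <- quantize_coefficients(co, 24)
  rng <- diff(range(co$C))
  expect_lt(max(abs(q24$C - co$C)), 1e-4 * rng)
  q10 <- quantize_coefficients(co, 10)
  expect_lt(max(abs(q10$C - co$C)), rng / 2^10)
  expect_true(q10$quantized)
  # constant coefficients: degenerate range passes through with a warning
  cc <- co; cc$C <- matrix(2, 4, 4)
  expect_warning(qc <- quantize_coefficients(cc, 10), "degenerate")
  expect_equal(qc$C, cc$C)
  # 10-bit quantization barely moves reconstruction accuracy
  sm <- align_spikes(test_spikes(), alignment_config("implant"))
  bb <- fixed2_basis()
  co8 <- compress(sm, bb, 8)
  rec <- test_recording()
  tmpl <- lapply(rec$templates, function(t) t[1, ])
  a0 <- reconstruction_accuracy(reconstruct(co8, bb), tmpl, sm$true_ids)
  a1 <- reconstruction_accuracy(reconstruct(quantize_coefficients(co8, 10), bb),
                                tmpl, sm$true_ids)
  expect_lt(abs(as.numeric(a0) - as.numeric(a1)), 0.005)
})

test_that("basis serialization round-trips through CSV + JSON", {
  b <- fixed2_basis()
  path <- file.path(tempdir(), "basis_test")
  write_basis(b, path)
  b2 <- read_basis(path)
  expect_equal(b2$W, b$W, tolerance = 1e-12)
  expect_identical(b2$kind, b$kind)
  expect_equal(b2$singular_values, b$singular_values, tolerance = 1e-10)
})
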