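# Evaluation measures: reconstruction accuracy, score, minimum-coefficient
# rule, median comparison, op counts and data rates.

test_that("reconstruction accuracy is 1 for templates and their shifts", {
  rec <- test_recording()
  tmpl <- lapply(rec$templates, function(t) t[1, ])
  X <- do.call(cbind, tmpl)
  expect_equal(as.numeric(reconstruction_accuracy(X, tmpl, 1:4)), 1,
               tolerance = 1e-12)
  shifted <- vapply(1:4, function(i)
    spikecodec:::shift_int(tmpl[[i]], c(3, -2, 5, -7)[i]), numeric(64))
  expect_equal(as.numeric(reconstruction_accuracy(shifted, tmpl, 1:4)), 1,
               tolerance = 1e-6)
})

test_that("reconstruction accuracy matches a brute-force lag search", {
  set.seed(30)
  tmpl <- list(40 * bandlimited_pulse(64, 4))
  spike <- tmpl[[1]] + stats::rnorm(64, sd = 4)
  got <- as.numeric(reconstruction_accuracy(matrix(spike), tmpl, 1L))
  # direct evaluation of the overlap-normalised correlation at every lag
  best <- -Inf
  for (lag in -10:10) {
    if (lag >= 0) { t_seg <- tmpl[[1]][(1 + lag):64]; s_seg <- spike[1:(64 - lag)] }
    else { t_seg <- tmpl[[1]][1:(64 + lag)]; s_seg <- spike[(1 - lag):64] }
    best <- max(best, sum(t_seg * s_seg) /
                  (sqrt(sum(t_seg^2)) * sqrt(sum(s_seg^2))))
  }
  expect_equal(got, best, tolerance = 1e-12)
  # zero-energy spike scores zero with a warning
  expect_warning(
    z <- reconstruction_accuracy(matrix(0, 64, 1), tmpl, 1L), "zero-energy")
  expect_equal(as.numeric(z), 0)
})

test_that("combined score is the mean of the two accuracies", {
  expect_equal(combined_score(1, 1), 1)
  expect_equal(combined_score(0, 0), 0)
  expect_equal(combined_score(0.8, 0.6), 0.7)
  expect_error(combined_score(1.2, 0.5), "0, 1")
  # monotone in each argument
  expect_gt(combined_score(0.9, 0.5), combined_score(0.8, 0.5))
  expect_gt(combined_score(0.9, 0.6), combined_score(0.9, 0.5))
})

test_that("minimum-coefficient rule follows the interpolated score curve", {
  expect_equal(min_coefficients(c(2, 4, 8), c(0.8, 0.8, 0.8)), 2L)
  Ls <- c(2, 4, 8, 16, 32)
  lm <- min_coefficients(Ls, c(0.5, 0.9, 0.905, 0.905, 0.905))
  expect_gt(lm, 2); expect_lte(lm, 8)
  # strictly rising to the end: only the largest L qualifies
  expect_equal(min_coefficients(Ls, c(0.2, 0.4, 0.6, 0.8, 1.0)), 32L)
  # never outside the evaluated range
  set.seed(31)
  for (i in 1:20) {
    sc <- stats::runif(5)
    lm <- min_coefficients(Ls, sc)
    expect_gte(lm, 2L); expect_lte(lm, 32L)
  }
  expect_error(min_coefficients(c(2, 4), c(1, 1)), "at least 3")
})

test_that("median comparison flags separated groups only", {
  set.seed(32)
  a <- stats::rnorm(19, 0.8, 0.02)
  same <- median_compare(a, a, seed = 1)
  expect_false(same$significant)
  b <- a - 10 * stats::sd(a)
  far <- median_compare(a, b, seed = 1)
  expect_true(far$significant)
  expect_error(median_compare(a[1:3], a), "at least 5")
  # verdict agrees with an independent percentile-bootstrap oracle
  oracle <- function(x, y, n_boot = 2000, conf = 0.95) {
    ci <- function(v, sd_seed) {
      set.seed(sd_seed)
      meds <- replicate(n_boot, stats::median(sample(v, replace = TRUE)))
      stats::quantile(meds, c((1 - conf) / 2, (1 + conf) / 2), names = FALSE)
    }
    ca <- ci(x, 101); cb <- ci(y, 102)
    ca[2] < cb[1] || cb[2] < ca[1]
  }
  c_mid <- a - 1.0 * stats::sd(a)   # moderate offset
  expect_identical(median_compare(a, c_mid, seed = 3)$significant,
                   oracle(a, c_mid))
  expect_identical(median_compare(a, b, seed = 3)$significant, oracle(a, b))
  expect_identical(median_compare(a, a, seed = 3)$significant, oracle(a, a))
})

test_that("operation counts follow the one-bit-addition cost model", {
  m <- cost_model()
  expect_equal(m$mult_cost, 10 * m$add_cost)
  zero <- cost_model(word_length = 0)
  oc0 <- op_count(1, "NEO", 8, zero)
  expect_equal(oc0$mops, 0)
  # NEO detection dominates: 220 ops/sample at 25 kHz = 5.5 MOPS
  neo1 <- op_count(1, "NEO", 8, m)
  expect_equal(neo1$detection / 1e6, 5.5)
  abs3 <- op_count(3, "ABS", 8, m)
  expect_equal(abs3$detection / 1e6, 0.25)
  expect_gt(abs3$alignment, 0)
  expect_equal(op_count(0, "ABS", 8, m)$compression, 0)
  ratio <- neo1$mops / abs3$mops
  expect_gt(ratio, 5); expect_lt(ratio, 20)
  expect_error(op_count(7, "ABS"), "architecture")
})

test_that("data-rate arithmetic reproduces the wireless budget figures", {
  r4 <- data_rate(L = 4)
  expect_equal(r4$bits_per_spike, 40)
  expect_equal(r4$raw_bits_per_spike, 640)
  expect_equal(r4$compression_factor, 16)
  expect_equal(r4$channel_rate, 1600)
  expect_equal(r4$raw_channel_rate, 250000)
  expect_equal(r4$channels_supported, 625)
  expect_equal(r4$raw_channels_supported, 4)
  expect_equal(data_rate(L = 8)$bits_per_spike, 80)
  expect_equal(100 * r4$raw_channel_rate, 25e6)
  expect_equal(r4$reduction, 1 - 1600 / 250000)
  expect_error(data_rate(L = 0), "positive")
})
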