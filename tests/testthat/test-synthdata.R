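# Ground-truth simulator: neuron placement, spike trains, templates,
# recording synthesis and SNR.

test_that("noise neurons fill the hollow cylinder uniformly in volume", {
  g <- geometry_config()
  nn <- place_noise_neurons(g, seed = 11)
  vol_cm3 <- pi * (g$cylinder_outer^2 - g$cylinder_inner^2) *
    2 * g$cylinder_halfheight * 1e-12
  expect_equal(length(nn), round(g$noise_density * vol_cm3))
  r <- vapply(nn, function(n) sqrt(sum(n$position[1:2]^2)), numeric(1))
  z <- vapply(nn, function(n) n$position[3], numeric(1))
  expect_true(all(r >= g$cylinder_inner - 1e-9 & r <= g$cylinder_outer + 1e-9))
  expect_true(all(abs(z) <= g$cylinder_halfheight + 1e-9))
  rates <- vapply(nn, function(n) n$mean_rate, numeric(1))
  expect_true(all(rates >= 1 & rates <= 50))

  # Monte-Carlo check of the radial law against the analytic uniform-in-
  # volume CDF F(r) = (r^2 - ri^2) / (ro^2 - ri^2), via chi-square over
  # equal-probability bins.
  big <- geometry_config(noise_density = 1.4e8) # ~10000 neurons
  rr <- vapply(place_noise_neurons(big, seed = 12),
               function(n) sqrt(sum(n$position[1:2]^2)), numeric(1))
  qs <- sqrt(seq(big$cylinder_inner^2, big$cylinder_outer^2, length.out = 21))
  counts <- table(cut(rr, qs, include.lowest = TRUE))
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 1e-4)
})

test_that("zero density yields no noise neurons", {
  g <- geometry_config(noise_density = 0)
  expect_length(place_noise_neurons(g, seed = 1), 0)
})

test_that("target neurons sit at the printed coordinates, scaled linearly", {
  t1 <- place_target_neurons(snr_scale = 1.0, seed = 5)
  pos <- t(vapply(t1, function(n) n$position, numeric(3)))
  expect_equal(pos, unname(target_base_coords()))
  t2 <- place_target_neurons(snr_scale = 2.0, seed = 5)
  expect_equal(t2[[1]]$position, c(20, 40, -4))
  expect_equal(t(vapply(t2, function(n) n$position, numeric(3))), pos * 2)
  rates <- vapply(t1, function(n) n$mean_rate, numeric(1))
  expect_true(all(rates >= 1 & rates <= 10))
  # mean x-y-plane distance from the array axis: ~20.4 um at scale 1, so
  # ~30.6 um at scale 1.5 (direct arithmetic on the coordinates)
  d15 <- vapply(place_target_neurons(snr_scale = 1.5, seed = 5),
                function(n) sqrt(sum(n$position[1:2]^2)), numeric(1))
  expect_equal(mean(d15), 30.6384, tolerance = 1e-4)
  expect_error(place_target_neurons(target_base_coords()[1:3, ], 1), "4 x 3")
})

test_that("spike trains have gamma ISIs at the nominal rate", {
  expect_length(sample_spike_train(0, 2, 10, seed = 1), 0)
  tr <- sample_spike_train(10, 2, 300, seed = 7)
  expect_true(all(diff(tr) >= 0.001))
  expect_true(all(tr >= 0 & tr < 300))
  # count within 3 SD of rate * duration (gamma renewal, CV^2 = 1/shape)
  expect_lt(abs(length(tr) - 3000), 3 * sqrt(3000 / 2) + 3)
  expect_identical(tr, sample_spike_train(10, 2, 300, seed = 7))
  expect_error(sample_spike_train(-1, 2, 10), "non-negative")
  # empirical rate converges (relative error < 5% at 1000 s)
  long <- sample_spike_train(5, 2, 1000, seed = 8)
  expect_lt(abs(length(long) / 1000 - 5) / 5, 0.05)
})

test_that("templates follow the 1/r point-source law with fixed shape", {
  params <- list(amp = 100, r0 = 20, k1 = 3, tau1 = 0.1, tau2 = 0.4,
                 ratio = 0.45, pre = 0, polarity = -1)
  nn <- neuron_spec(c(0, 0, 0), params, mean_rate = 5)
  w1 <- waveform_at_site(nn, c(20, 0, 0))
  w2 <- waveform_at_site(nn, c(40, 0, 0))
  expect_equal(max(abs(w1)), 100)
  expect_equal(w2 * 2, w1, tolerance = 1e-12)
  expect_error(waveform_at_site(nn, c(0, 0, 0)), "coincides")
  # different waveform parameters give genuinely different shapes
  nn2 <- nn; nn2$waveform_params$tau1 <- 0.2; nn2$waveform_params$ratio <- 0.1
  w3 <- waveform_at_site(nn2, c(20, 0, 0))
  cc <- max(abs(stats::ccf(as.numeric(w1), as.numeric(w3), lag.max = 20,
                           plot = FALSE)$acf))
  expect_lt(cc, 1 - 1e-3)
})

test_that("recording synthesis is linear superposition plus filtered noise", {
  g <- geometry_config(noise_density = 0)
  tg <- place_target_neurons(seed = 3)
  a <- synthesize_recording(g, tg[1:2], list(), 5, 0, seed = 9, channels = 10)
  b <- synthesize_recording(g, tg[3:4], list(), 5, 0, seed = 9, channels = 10)
  ab <- synthesize_recording(g, tg, list(), 5, 0, seed = 9, channels = 10)
  expect_equal(a$samples + b$samples, ab$samples, tolerance = 1e-12)

  # one neuron, no noise: the signal is the filtered template at true times
  rec <- noiseless_recording()
  t0 <- floor(rec$true_spike_times[[1]] * rec$fs) + 1
  t0 <- t0[t0 + 63 <= ncol(rec$samples) &
             c(diff(t0) > 64, TRUE) & c(TRUE, diff(t0) > 64)]
  tmpl <- rec$templates[[1]][1, ]
  for (s in t0[1:3])
    expect_equal(rec$samples[1, s:(s + 63)], tmpl, tolerance = 0.02)

  # pure thermal noise: channel SD matches independently filtered white noise
  noise <- synthesize_recording(g, list(), list(), 5, thermal_sigma = 2,
                                seed = 10, channels = 10)
  set.seed(10)
  bf <- signal::butter(2, c(300, 5000) / 12500, type = "pass")
  ref <- signal::filtfilt(bf, stats::rnorm(5 * 25000, 0, 2))
  expect_equal(stats::sd(noise$samples[1, ]), stats::sd(ref), tolerance = 0.05)
})

test_that("SNR is scale-invariant and decreases with the coordinate scale", {
  rec <- test_recording()
  s1 <- estimate_snr(rec)
  scaled <- rec
  scaled$samples <- rec$samples * 3.7
  expect_equal(estimate_snr(scaled), s1, tolerance = 1e-10)
  rec2 <- test_recording("low")
  expect_lt(estimate_snr(rec2), s1)
  expect_gt(s1 / estimate_snr(rec2), 1.5)
})

test_that("surrogate library is frozen, positive-norm and low-rank-dominated", {
  lib <- make_surrogate_library()
  expect_identical(lib, make_surrogate_library())
  expect_equal(dim(lib), c(64, 500))
  expect_true(all(colSums(lib^2) > 0))
  sv <- svd(lib, nu = 0, nv = 0)$d
  expect_gt(sum(sv[1:4]^2) / sum(sv^2), 0.8)
  expect_error(make_surrogate_library(32), "at least")
})

test_that("model-point library spans the four target shapes with 1/r decay", {
  lib <- make_model_point_library(n_per_neuron = 50, seed = 2)
  expect_equal(dim(lib), c(64, 200))
  expect_identical(lib, make_model_point_library(n_per_neuron = 50, seed = 2))
  # each column is proportional to one of the four model shapes
  shapes <- vapply(1:4, function(i)
    spikecodec:::template_shape(spikecodec:::target_waveform_params(i)),
    numeric(64))
  cors <- apply(abs(stats::cor(lib[, c(1, 60, 120, 190)], shapes)), 1, max)
  expect_true(all(cors > 1 - 1e-10))
})
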