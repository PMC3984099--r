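# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A short high-SNR single-channel recording for unit tests.
test_recording <- function(level = "high", seed = 1, duration = 20) {
  cached(paste("rec", level, seed, duration),
         make_test_recording(level, duration = duration, seed = seed))
}

test_spikes <- function(method = "ABS", level = "high", seed = 1) {
  cached(paste("spk", method, level, seed),
         extract_with_jitter(test_recording(level, seed), 1,
                             detector_config(method)))
}

fixed2_basis <- function() {
  cached("fixed2", build_fixed_basis(make_surrogate_library(), "fixed2"))
}

fixed1_basis <- function() {
  cached("fixed1", build_fixed_basis(make_model_point_library(), "fixed1"))
}

# A clean band-limited test pulse (no energy near Nyquist), centred.
bandlimited_pulse <- function(n = 64, width = 4) {
  t <- seq_len(n) - n / 2
  exp(-t^2 / (2 * width^2))
}

# A small noiseless spike matrix: one template at known positions in a flat
# signal, extracted via ground truth.
noiseless_recording <- function(n_spikes = 12, duration = 2) {
  cached(paste("clean", n_spikes, duration), {
    g <- geometry_config(noise_density = 0)
    tg <- place_target_neurons(seed = 3)[1]
    tg[[1]]$mean_rate <- n_spikes / duration * 1.1
    synthesize_recording(g, tg, list(), duration = duration,
                         thermal_sigma = 0, seed = 4, channels = 10)
  })
}
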