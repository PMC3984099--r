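# Ground-truth synthetic recordings: a linear 19-site array along the z axis,
# four target neurons close to the array, and a shell of background ("noise")
# neurons in a hollow cylinder concentric with the array.

#' Geometry and acquisition configuration for the synthetic recordings
#'
#' Describes the electrode array, the hollow cylindrical volume that holds
#' the background neurons, and the acquisition settings. The array lies along
#' the z axis; radial distances are measured in the x-y plane.
#'
#' @param n_electrodes number of evenly spaced electrode sites.
#' @param electrode_spacing spacing along the array axis, micrometres.
#' @param cylinder_inner,cylinder_outer radial bounds of the hollow cylinder
#'   holding noise neurons, micrometres.
#' @param cylinder_halfheight half-height of the cylinder, micrometres.
#' @param noise_density background neuron density, neurons per cubic
#'   centimetre.
#' @param snr_scale multiplier applied to the target-neuron coordinates; 1.0,
#'   1.5 and 2.0 give the high-, medium- and low-SNR conditions.
#' @param fs sampling rate, Hz.
#' @param band passband edges of the acquisition bandpass filter, Hz.
#' @return an object of class `geometry_config`.
#' @export
geometry_config <- function(n_electrodes = 19,
                            electrode_spacing = 50,
                            cylinder_inner = 120,
                            cylinder_outer = 250,
                            cylinder_halfheight = 250,
                            noise_density = 5e6,
                            snr_scale = 1.0,
                            fs = 25000,
                            band = c(300, 5000)) {
  if (cylinder_inner >= cylinder_outer)
    stop("cylinder_inner must be smaller than cylinder_outer")
  if (noise_density < 0) stop("noise_density must be non-negative")
  if (snr_scale <= 0) stop("snr_scale must be positive")
  z <- (seq_len(n_electrodes) - (n_electrodes + 1) / 2) * electrode_spacing
  sites <- cbind(x = 0, y = 0, z = z)
  structure(list(
    electrode_positions = sites,
    electrode_spacing = electrode_spacing,
    cylinder_inner = cylinder_inner,
    cylinder_outer = cylinder_outer,
    cylinder_halfheight = cylinder_halfheight,
    noise_density = noise_density,
    snr_scale = snr_scale,
    fs = fs,
    band = band
  ), class = "geometry_config")
}

#' Single-neuron specification
#'
#' @param position 3-vector, micrometres.
#' @param waveform_params list with fields `amp` (amplitude at the reference
#'   distance `r0`), `r0` (reference distance, micrometres), `tau1`, `tau2`
#'   (time constants of the fast and slow waveform phases, ms), `ratio`
#'   (relative size of the slow phase) and `polarity` (+1 or -1).
#' @param mean_rate mean firing rate, spikes/second.
#' @param gamma_shape shape parameter of the gamma inter-spike-interval
#'   distribution.
#' @param train_seed RNG seed used for this neuron's spike train, so that a
#'   neuron produces the same train regardless of which neuron set it is
#'   synthesized with.
#' @return an object of class `neuron_spec`.
#' @export
neuron_spec <- function(position, waveform_params, mean_rate,
                        gamma_shape = 2, train_seed = 1L) {
  position <- as.numeric(position)
  if (length(position) != 3 || any(!is.finite(position)))
    stop("position must be a finite 3-vector")
  if (mean_rate < 0) stop("mean_rate must be non-negative")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  structure(list(
    position = position,
    waveform_params = waveform_params,
    mean_rate = mean_rate,
    gamma_shape = gamma_shape,
    train_seed = as.integer(train_seed)
  ), class = "neuron_spec")
}

#' Reference coordinates of the four target neurons (high-SNR condition)
#'
#' Positions in micrometres relative to the centre of the electrode array;
#' their mean x-y-plane distance from the array axis is approximately 20 um.
#'
#' @return a 4 x 3 numeric matrix.
#' @export
target_base_coords <- function() {
  rbind(c(10, 20, -2),
        c(-2, 18, 20),
        c(-20, -5, -10),
        c(16, -13, 15))
}

# The four target-neuron waveform models: clearly distinct sharpness, time
# constants, after-potential size and leading (capacitive) phase so the
# units are separable in feature space, as the compartmental models they
# stand in for are. All dominant-negative, as is typical of extracellular
# somatic spikes.
target_waveform_params <- function(i) {
  amp   <- c(100, 110, 115, 95)
  k1    <- c(2, 7, 3, 3)        # sharpness of the main phase
  tau1  <- c(0.16, 0.045, 0.10, 0.12)
  tau2  <- c(0.70, 0.50, 0.35, 0.22)
  ratio <- c(0.70, 0.05, 0.45, 0.55)
  pre   <- c(0, 0.55, 0, 0)     # leading positive phase, fraction of peak
  pol   <- c(-1, -1, 1, -1)     # unit 3 is positive-dominant (dendritic)
  list(amp = amp[i], r0 = 20, k1 = k1[i], tau1 = tau1[i], tau2 = tau2[i],
       ratio = ratio[i], pre = pre[i], polarity = pol[i])
}

#' Place the four target neurons
#'
#' The reference coordinates are scaled element-wise by `snr_scale`; moving
#' the neurons away from the array lowers their amplitudes (1/r decay) while
#' the noise-neuron shell stays put, which lowers the SNR. Mean rates are
#' drawn uniformly between 1 and 10 spikes/second.
#'
#' @param base_coords 4 x 3 matrix of reference positions (micrometres).
#' @param snr_scale positive coordinate multiplier.
#' @param seed RNG seed for rates and per-neuron train seeds.
#' @return list of four [neuron_spec] objects.
#' @export
place_target_neurons <- function(base_coords = target_base_coords(),
                                 snr_scale = 1.0, seed = 1L) {
  if (!is.matrix(base_coords) || nrow(base_coords) != 4 || ncol(base_coords) != 3)
    stop("base_coords must be a 4 x 3 matrix")
  if (snr_scale <= 0) stop("snr_scale must be positive")
  set.seed(seed)
  rates <- stats::runif(4, 1, 10)
  train_seeds <- sample.int(1e6, 4)
  lapply(seq_len(4), function(i) {
    neuron_spec(position = base_coords[i, ] * snr_scale,
                waveform_params = target_waveform_params(i),
                mean_rate = rates[i],
                gamma_shape = 2,
                train_seed = train_seeds[i])
  })
}

#' Place background neurons uniformly in the hollow cylinder
#'
#' The neuron count is `round(density * volume)`; positions are uniform in
#' volume (radius drawn with the square-root transform), mean rates uniform
#' between 1 and 50 spikes/second, and each neuron gets randomised waveform
#' time constants from the same biphasic family as the target models.
#'
#' @param geometry a [geometry_config].
#' @param seed RNG seed.
#' @return list of [neuron_spec] objects (possibly empty).
#' @export
place_noise_neurons <- function(geometry, seed = 1L) {
  stopifnot(inherits(geometry, "geometry_config"))
  ri <- geometry$cylinder_inner
  ro <- geometry$cylinder_outer
  hh <- geometry$cylinder_halfheight
  if (geometry$noise_density < 0 || ri >= ro || hh <= 0)
    stop("invalid noise-neuron geometry")
  vol_um3 <- pi * (ro^2 - ri^2) * (2 * hh)
  vol_cm3 <- vol_um3 * 1e-12
  n <- round(geometry$noise_density * vol_cm3)
  if (n == 0) return(list())
  set.seed(seed)
  r <- sqrt(stats::runif(n, ri^2, ro^2))
  theta <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, -hh, hh)
  rates <- stats::runif(n, 1, 50)
  amp <- stats::runif(n, 60, 120)
  tau1 <- stats::runif(n, 0.07, 0.14)
  tau2 <- stats::runif(n, 0.3, 0.6)
  ratio <- stats::runif(n, 0.3, 0.55)
  train_seeds <- sample.int(1e6, n)
  lapply(seq_len(n), function(i) {
    neuron_spec(
      position = c(r[i] * cos(theta[i]), r[i] * sin(theta[i]), z[i]),
      waveform_params = list(amp = amp[i], r0 = 20, tau1 = tau1[i],
                             tau2 = tau2[i], ratio = ratio[i], polarity = -1),
      mean_rate = rates[i],
      gamma_shape = 2,
      train_seed = train_seeds[i])
  })
}

#' Draw a spike train with gamma-distributed inter-spike intervals
#'
#' Intervals are gamma with the given shape and mean `1/rate`, floored at the
#' refractory period. A zero rate gives an empty train.
#'
#' @param rate mean firing rate, spikes/second.
#' @param gamma_shape gamma shape parameter (dimensionless, > 0).
#' @param duration recording length, seconds.
#' @param refractory_floor minimum inter-spike interval, seconds.
#' @param seed RNG seed.
#' @return strictly increasing spike times in `[0, duration)`, seconds.
#' @export
sample_spike_train <- function(rate, gamma_shape = 2, duration,
                               refractory_floor = 0.001, seed = 1L) {
  if (rate < 0) stop("rate must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  if (rate == 0) return(numeric(0))
  set.seed(seed)
  scale <- 1 / (rate * gamma_shape)
  times <- numeric(0)
  t_last <- 0
  # draw in chunks until the train covers the recording
  repeat {
    n_chunk <- max(16L, ceiling((duration - t_last) * rate * 1.5))
    isi <- pmax(stats::rgamma(n_chunk, shape = gamma_shape, scale = scale),
                refractory_floor)
    new <- t_last + cumsum(isi)
    times <- c(times, new)
    t_last <- times[length(times)]
    if (t_last >= duration) break
  }
  times[times < duration]
}

# Unit-peak spike template shape: an optional small leading positive phase,
# a sharp main phase, and a slower after-phase of opposite sign, sampled on
# an n-sample window. The main peak lands on `peak_index`. Shape is
# distance-invariant; only the amplitude decays with distance (1/r point
# source).
template_shape <- function(params, fs = 25000, n = 64, peak_index = 17) {
  k1 <- if (is.null(params$k1)) 3 else params$k1
  pre <- if (is.null(params$pre)) 0 else params$pre
  tm <- (seq_len(n) - 1) / fs * 1000 # ms
  # dgamma(shape = k) peaks at (k - 1) * scale; offset so the main peak
  # lands on the registration sample
  t0 <- (peak_index - 1) / fs * 1000 - (k1 - 1) * params$tau1
  tt <- tm - t0
  b1 <- stats::dgamma(tt, shape = k1, scale = params$tau1)
  b2 <- stats::dgamma(tt, shape = 3, scale = params$tau2)
  s <- -b1 / max(b1) + params$ratio * b2 / max(b2)
  if (pre > 0) {
    b0 <- stats::dgamma(-(tt - 0.08), shape = 3, scale = 0.06)
    if (max(b0) > 0) s <- s + pre * b0 / max(b0)
  }
  s <- s / max(abs(s))
  if (!is.null(params$polarity) && params$polarity > 0) s <- -s
  s
}

#' Noiseless template of a neuron at an electrode site
#'
#' The template is the neuron's biphasic waveform shape scaled by
#' `amp * r0 / distance` (monopolar point-source decay). Shape does not vary
#' with distance.
#'
#' @param neuron a [neuron_spec].
#' @param site 3-vector electrode position, micrometres.
#' @param fs sampling rate, Hz.
#' @param window_len template length, samples.
#' @return numeric template vector of length `window_len`.
#' @export
waveform_at_site <- function(neuron, site, fs = 25000, window_len = 64) {
  d <- sqrt(sum((as.numeric(site) - neuron$position)^2))
  if (d == 0) stop("electrode site coincides with the neuron position")
  p <- neuron$waveform_params
  amp <- p$amp * (p$r0 / d)
  amp * template_shape(p, fs = fs, n = window_len)
}

# Zero-phase 4th-order Butterworth bandpass, the acquisition filter.
bandpass_filter <- function(x, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Filtered version of a template as it appears in a bandpassed recording.
filtered_template <- function(tmpl, fs, band, pad = 256) {
  y <- bandpass_filter(c(numeric(pad), tmpl, numeric(pad)), fs, band)
  y[(pad + 1):(pad + length(tmpl))]
}

#' Synthesize a multi-channel extracellular recording with known ground truth
#'
#' Each channel is the superposition, over all neurons, of the neuron's
#' site-specific template placed at its spike times, plus white Gaussian
#' thermal noise, bandpass filtered (zero phase) between the band edges of
#' the geometry. Ground-truth spike times, identities and the filtered
#' noiseless templates of the target neurons are stored alongside the
#' samples.
#'
#' @param geometry a [geometry_config].
#' @param targets list of target [neuron_spec]s (ground truth is kept for
#'   these).
#' @param noise_neurons list of background [neuron_spec]s (no ground truth
#'   kept).
#' @param duration recording length, seconds.
#' @param thermal_sigma SD of the additive white thermal noise (same
#'   amplitude units as the templates), applied before filtering.
#' @param seed RNG seed for the thermal noise.
#' @param channels integer indices of the electrode sites to synthesize
#'   (default all); synthesizing a single site keeps long parameter studies
#'   cheap.
#' @param window_len spike template length, samples.
#' @return an object of class `recording` with fields `samples`
#'   (channels x time), `fs`, `band`, `duration`, `true_spike_times` (list
#'   per target neuron, seconds), `neuron_ids`, `templates` (list per target
#'   neuron of channels x window matrices, filtered), `channel_sites`,
#'   `geometry`.
#' @export
synthesize_recording <- function(geometry, targets, noise_neurons = list(),
                                 duration, thermal_sigma = 0, seed = 1L,
                                 channels = NULL, window_len = 64) {
  stopifnot(inherits(geometry, "geometry_config"))
  if (duration <= 0) stop("duration must be positive")
  fs <- geometry$fs
  n_samp <- round(duration * fs)
  sites <- geometry$electrode_positions
  if (is.null(channels)) channels <- seq_len(nrow(sites))
  n_ch <- length(channels)
  samples <- matrix(0, nrow = n_ch, ncol = n_samp)

  all_neurons <- c(targets, noise_neurons)
  trains <- lapply(all_neurons, function(nn)
    sample_spike_train(nn$mean_rate, nn$gamma_shape, duration,
                       seed = nn$train_seed))

  for (j in seq_along(all_neurons)) {
    nn <- all_neurons[[j]]
    tr <- trains[[j]]
    if (length(tr) == 0) next
    t0 <- floor(tr * fs) + 1L
    t0 <- t0[t0 + window_len - 1L <= n_samp]
    if (length(t0) == 0) next
    shape <- template_shape(nn$waveform_params, fs = fs, n = window_len)
    for (ci in seq_len(n_ch)) {
      site <- sites[channels[ci], ]
      d <- sqrt(sum((site - nn$position)^2))
      amp <- nn$waveform_params$amp * (nn$waveform_params$r0 / d)
      tmpl <- amp * shape
      # t0 is strictly increasing (refractory floor), so the indices within
      # each vectorized add are unique and accumulation is exact
      for (k in 0:(window_len - 1L)) {
        samples[ci, t0 + k] <- samples[ci, t0 + k] + tmpl[k + 1L]
      }
    }
  }

  set.seed(seed)
  if (thermal_sigma > 0) {
    for (ci in seq_len(n_ch))
      samples[ci, ] <- samples[ci, ] + stats::rnorm(n_samp, 0, thermal_sigma)
  }
  for (ci in seq_len(n_ch))
    samples[ci, ] <- bandpass_filter(samples[ci, ], fs, geometry$band)

  templates <- lapply(targets, function(nn) {
    tm <- t(vapply(channels, function(ch) {
      filtered_template(
        waveform_at_site(nn, sites[ch, ], fs = fs, window_len = window_len),
        fs, geometry$band)
    }, numeric(window_len)))
    rownames(tm) <- channels
    tm
  })

  structure(list(
    samples = samples,
    fs = fs,
    band = geometry$band,
    duration = duration,
    true_spike_times = trains[seq_along(targets)],
    neuron_ids = seq_along(targets),
    templates = templates,
    channel_sites = channels,
    geometry = geometry,
    thermal_sigma = thermal_sigma,
    seed = seed
  ), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %.1f s at %d Hz, %d target neuron(s)\n",
              nrow(x$samples), x$duration, x$fs, length(x$neuron_ids)))
  cat(sprintf("  band %g-%g Hz, snr_scale %.2f, %s true spikes\n",
              x$band[1], x$band[2], x$geometry$snr_scale,
              sum(lengths(x$true_spike_times))))
  invisible(x)
}

#' Peak-to-peak SNR of target neurons in a recording
#'
#' SNR of one neuron at one channel is the peak-to-peak amplitude of its
#' mean extracted waveform divided by the robust (median-based) noise SD of
#' that channel, `median(|x|) / 0.6745`. With `neuron_id = NULL` the mean
#' over the target neurons is returned, which is the per-recording summary
#' figure.
#'
#' @param recording a `recording`.
#' @param neuron_id target neuron id, or `NULL` for the mean over targets.
#' @param channel channel row index into `recording$samples`.
#' @param window_len spike window, samples.
#' @return SNR value (dimensionless).
#' @export
estimate_snr <- function(recording, neuron_id = NULL, channel = 1,
                         window_len = 64) {
  x <- recording$samples[channel, ]
  sig <- noise_sigma(x)
  if (sig == 0) stop("noise SD estimate is zero; SNR undefined")
  one <- function(id) {
    tr <- recording$true_spike_times[[id]]
    if (length(tr) == 0) stop("neuron has no spikes on record")
    t0 <- floor(tr * recording$fs) + 1L
    t0 <- t0[t0 + window_len - 1L <= length(x)]
    w <- vapply(t0, function(s) x[s:(s + window_len - 1L)],
                numeric(window_len))
    mw <- rowMeans(w)
    (max(mw) - min(mw)) / sig
  }
  ids <- if (is.null(neuron_id)) recording$neuron_ids else neuron_id
  mean(vapply(ids, one, numeric(1)))
}

#' Surrogate generic spike-waveform library
#'
#' Generates a deterministic library of spike-like waveforms from a
#' Gaussian-derivative family: a first-derivative-of-Gaussian main phase of
#' random width, an after-potential bump of random size, lag and width, and
#' an optional small leading bump; a minority of waveforms are
#' positive-dominant. The family is deliberately different from the
#' difference-of-gammas model used for the test-data neurons, so a fixed
#' compression basis derived from this library is unrelated to the
#' recordings it is later used to compress. The default seed is frozen; the
#' same seed always yields a bit-identical matrix.
#'
#' @param n_waveforms number of library waveforms (must be at least
#'   `window_len` so a full SVD basis can be derived from it).
#' @param family_params list of ranges (all times in ms): `width` and
#'   `centre` of the main phase, `after_amp`, `after_lag`, `after_width` of
#'   the after-potential, `pre_amp`, `pre_lag`, `pre_width` of the leading
#'   bump, and `p_positive`, the proportion of positive-dominant waveforms.
#' @param seed frozen RNG seed of the library version.
#' @param fs sampling rate, Hz.
#' @param window_len waveform length, samples.
#' @return a `window_len x n_waveforms` numeric matrix with unit-peak
#'   columns.
#' @export
make_surrogate_library <- function(n_waveforms = 500,
                                   family_params = list(
                                     width = c(0.08, 0.45),
                                     centre = c(0.55, 0.75),
                                     after_amp = c(0, 0.8),
                                     after_lag = c(0.25, 1.2),
                                     after_width = c(0.25, 0.7),
                                     pre_amp = c(0, 0.5),
                                     pre_lag = c(0.15, 0.4),
                                     pre_width = c(0.06, 0.2),
                                     p_positive = 0.2),
                                   seed = 20140411,
                                   fs = 25000, window_len = 64) {
  if (n_waveforms < window_len)
    stop("n_waveforms must be at least window_len for a full-rank basis")
  set.seed(seed %% .Machine$integer.max)
  fp <- family_params
  tm <- (seq_len(window_len) - 1) / fs * 1000
  ru <- function(r) stats::runif(n_waveforms, r[1], r[2])
  w0 <- ru(fp$width); c0 <- ru(fp$centre)
  a2 <- ru(fp$after_amp); l2 <- ru(fp$after_lag); w2 <- ru(fp$after_width)
  a3 <- ru(fp$pre_amp); l3 <- ru(fp$pre_lag); w3 <- ru(fp$pre_width)
  pol <- sample(c(-1, 1), n_waveforms, replace = TRUE,
                prob = c(1 - fp$p_positive, fp$p_positive))
  vapply(seq_len(n_waveforms), function(i) {
    main <- -(tm - c0[i]) / w0[i] * exp(-((tm - c0[i])^2) / (2 * w0[i]^2))
    after <- a2[i] * exp(-((tm - c0[i] - l2[i])^2) / (2 * w2[i]^2))
    pre <- a3[i] * exp(-((tm - c0[i] + l3[i])^2) / (2 * w3[i]^2))
    s <- pol[i] * (main / max(abs(main)) - after + pre)
    s / max(abs(s))
  }, numeric(window_len))
}

#' Synthesize a test recording at one of the three SNR conditions
#'
#' Convenience constructor encoding the study conditions: the four target
#' neurons at their reference coordinates scaled by 1.0 (`"high"`), 1.5
#' (`"medium"`) or 2.0 (`"low"`), the standard noise-neuron shell, and the
#' default thermal noise level. One derived seed drives the neuron
#' placement, spike trains and thermal noise, so a (level, seed) pair fully
#' determines the recording.
#'
#' @param snr_level `"high"`, `"medium"` or `"low"`.
#' @param duration recording length, seconds.
#' @param seed RNG seed.
#' @param channels electrode sites to synthesize (default: the single site
#'   at the array centre).
#' @param thermal_sigma thermal-noise SD.
#' @return a `recording`.
#' @export
make_test_recording <- function(snr_level = c("high", "medium", "low"),
                                duration = 60, seed = 1L, channels = 10,
                                thermal_sigma = 3) {
  snr_level <- match.arg(snr_level)
  scale <- c(high = 1.0, medium = 1.5, low = 2.0)[[snr_level]]
  g <- geometry_config(snr_scale = scale)
  targets <- place_target_neurons(snr_scale = scale, seed = seed * 7L + 1L)
  noise <- place_noise_neurons(g, seed = seed * 7L + 2L)
  synthesize_recording(g, targets, noise, duration = duration,
                       thermal_sigma = thermal_sigma, seed = seed * 7L + 3L,
                       channels = channels)
}

#' Model-derived spike-waveform library for the first fixed basis
#'
#' Computes the waveform measured at random points surrounding each of the
#' four target-neuron models (default 10 000 points per neuron, 40 000
#' waveforms in total). Because the model's waveform shape is
#' distance-invariant with 1/r amplitude decay, this library spans the same
#' four shapes as the test data without being derived from any particular
#' test recording.
#'
#' @param n_per_neuron measurement points around each model neuron.
#' @param radius_range distances of the measurement points from each neuron,
#'   micrometres.
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @param window_len waveform length, samples.
#' @return a `window_len x (4 * n_per_neuron)` matrix.
#' @export
make_model_point_library <- function(n_per_neuron = 10000,
                                     radius_range = c(15, 100),
                                     seed = 1L, fs = 25000, window_len = 64) {
  set.seed(seed)
  cols <- lapply(seq_len(4), function(i) {
    p <- target_waveform_params(i)
    shape <- template_shape(p, fs = fs, n = window_len)
    # uniform-in-volume distances within the shell
    d <- (stats::runif(n_per_neuron, radius_range[1]^3, radius_range[2]^3))^(1 / 3)
    amps <- p$amp * (p$r0 / d)
    outer(shape, amps)
  })
  do.call(cbind, cols)
}
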