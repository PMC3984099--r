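# Plain interchange formats: recordings as flat little-endian float32 binary
# with a JSON sidecar and CSV ground truth; spike matrices and bases as CSV
# plus JSON metadata.

#' Write a recording bundle to disk
#'
#' Writes `<path>.f32` (channel-major little-endian 32-bit floats),
#' `<path>.json` (sampling rate, channels, duration, band, seed, geometry
#' summary), `<path>_ground_truth.csv` (columns `time_s`, `neuron_id`) and
#' one `<path>_template_<id>.csv` per target neuron (channels x samples).
#'
#' @param recording a `recording`.
#' @param path file path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$samples)), con, size = 4,
           endian = "little")
  meta <- list(fs = recording$fs,
               n_channels = nrow(recording$samples),
               n_samples = ncol(recording$samples),
               duration = recording$duration,
               band = recording$band,
               seed = recording$seed,
               thermal_sigma = recording$thermal_sigma,
               snr_scale = recording$geometry$snr_scale,
               channel_sites = recording$channel_sites)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  gt <- data.frame(
    time_s = unlist(recording$true_spike_times, use.names = FALSE),
    neuron_id = rep(recording$neuron_ids,
                    lengths(recording$true_spike_times)))
  gt <- gt[order(gt$time_s), ]
  utils::write.csv(gt, paste0(path, "_ground_truth.csv"), row.names = FALSE)
  for (id in recording$neuron_ids) {
    utils::write.csv(recording$templates[[id]],
                     sprintf("%s_template_%d.csv", path, id),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a recording bundle written by [write_recording]
#'
#' @param path file path prefix used when writing.
#' @return a `recording` (geometry is restored as a summary, not the full
#'   [geometry_config]).
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".f32"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples,
                  size = 4, endian = "little")
  samples <- matrix(vals, nrow = meta$n_channels, byrow = TRUE)
  gt <- utils::read.csv(paste0(path, "_ground_truth.csv"))
  ids <- sort(unique(gt$neuron_id))
  trains <- lapply(ids, function(id) gt$time_s[gt$neuron_id == id])
  templates <- lapply(ids, function(id) {
    m <- as.matrix(utils::read.csv(sprintf("%s_template_%d.csv", path, id)))
    dimnames(m) <- NULL
    m
  })
  structure(list(samples = samples, fs = meta$fs, band = meta$band,
                 duration = meta$duration, true_spike_times = trains,
                 neuron_ids = ids, templates = templates,
                 channel_sites = meta$channel_sites,
                 geometry = list(snr_scale = meta$snr_scale),
                 thermal_sigma = meta$thermal_sigma, seed = meta$seed),
            class = "recording")
}

#' Write a spike matrix as CSV plus JSON metadata
#'
#' @param spikes a `spike_matrix`.
#' @param path file path prefix.
#' @return `path`, invisibly.
#' @export
write_spike_matrix <- function(spikes, path) {
  utils::write.csv(spikes$waveforms, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fs = spikes$fs, detection_index = spikes$detection_index,
         true_ids = spikes$true_ids, retained_mask = spikes$retained_mask,
         threshold = spikes$threshold, method = spikes$method),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spike matrix written by [write_spike_matrix]
#'
#' @param path file path prefix.
#' @return a `spike_matrix`.
#' @export
read_spike_matrix <- function(path) {
  w <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  dimnames(w) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(waveforms = w,
                 detection_index = meta$detection_index,
                 true_ids = meta$true_ids,
                 fs = meta$fs,
                 retained_mask = meta$retained_mask,
                 threshold = meta$threshold,
                 method = meta$method,
                 window = nrow(w),
                 pre_detection = 16L),
            class = "spike_matrix")
}

#' Write a compression basis as CSV plus JSON metadata
#'
#' @param basis a `compression_basis`.
#' @param path file path prefix.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  utils::write.csv(basis$W, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(kind = basis$kind, M = nrow(basis$W),
         singular_values = basis$singular_values,
         interpolation_required = basis$interpolation_required),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a compression basis written by [write_basis]
#'
#' @param path file path prefix.
#' @return a `compression_basis`.
#' @export
read_basis <- function(path) {
  W <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  dimnames(W) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_basis(W, meta$kind,
            singular_values = meta$singular_values,
            interpolation_required = isTRUE(meta$interpolation_required))
}
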