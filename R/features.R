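# Per-window feature layouts.
#
# Two feature views are produced from the same 64 s window:
#  * the network view: 64 one-second non-overlapping STFT frames x 34
#    equal-width frequency bands (0-128 Hz) of channel-averaged log band
#    power, flattened frame-major to the model's 2176-dim input;
#  * the factor-analysis view: the spectrogram magnitudes averaged over time
#    frames and concatenated over channels (one value per channel/bin pair),
#    which keeps the feature dimension manageable for the common-factor model.

N_FRAMES <- 64L
N_BANDS <- 34L

#' Network input features for one window
#'
#' @param window_data channels x samples matrix holding one 64 s window.
#' @param fs sampling rate in Hz (must be 256).
#' @param n_bands number of equal-width frequency bands.
#' @return an `n_frames x n_bands` matrix of log10 band powers; flatten with
#'   [flatten_features()] before feeding the network.
#' @export
window_features <- function(window_data, fs = 256, n_bands = N_BANDS) {
  cfg <- stft_config(fs = fs, segment_len = fs, overlap = 0)
  sp <- stft_spectrogram(window_data, cfg)
  power <- apply(sp$magnitudes^2, c(2, 3), mean)     # bins x frames, channel mean
  band_of <- pmin(n_bands, floor(sp$freq_axis / (fs / 2) * n_bands) + 1L)
  bands <- rowsum(power, band_of)                    # n_bands x frames
  t(log10(bands + 1e-12))                            # frames x bands
}

#' Flatten a frames x bands feature matrix to the model input vector
#' @param feat matrix from [window_features()].
#' @return numeric vector of length `nrow * ncol` (frame-major layout).
#' @export
flatten_features <- function(feat) as.numeric(t(feat))

#' Reshape a flat model input vector back to frames x bands
#' @param v numeric vector of length `n_frames * n_bands`.
#' @param n_bands number of frequency bands.
#' @return frames x bands matrix.
#' @export
unflatten_features <- function(v, n_bands = N_BANDS) {
  matrix(v, ncol = n_bands, byrow = TRUE)
}

#' Frame-averaged spectrogram vector for factor analysis
#'
#' @param window_data channels x samples matrix holding one window.
#' @param cfg an [stft_config()].
#' @return numeric vector of length `channels * freq_bins`.
#' @export
fa_window_vector <- function(window_data, cfg = stft_config()) {
  sp <- stft_spectrogram(window_data, cfg)
  as.numeric(t(apply(sp$magnitudes, c(1, 2), mean)))
}

#' Build a labelled window dataset from one record
#'
#' Runs the preprocessing chain on a record: filtering, segmentation,
#' labelling against the record's annotations, and per-window network
#' features.
#'
#' @param record an [eeg_record()] at 256 Hz.
#' @param preictal_horizon_s,min_interictal_gap_s labelling parameters, see
#'   [label_windows()].
#' @param window_s,step_s segmentation parameters.
#' @param filter logical; apply [apply_filters()] first (default TRUE).
#' @return list with `x` (n_windows x 2176 feature matrix), `y` (0/1 labels),
#'   `start_s`, `patient_id`.
#' @export
build_window_dataset <- function(record, preictal_horizon_s = 1200,
                                 min_interictal_gap_s = 3600,
                                 window_s = 64, step_s = 32, filter = TRUE) {
  if (record$fs != 256) record <- resample_to_256(record)
  if (filter) record <- apply_filters(record)
  starts <- segment_windows(record, window_s, step_s)
  lab <- label_windows(starts, record$annotations, preictal_horizon_s,
                       min_interictal_gap_s, window_s)
  x <- matrix(0, nrow(lab), N_FRAMES * N_BANDS)
  for (i in seq_len(nrow(lab))) {
    idx <- round(lab$start_s[i] * record$fs) + seq_len(window_s * record$fs)
    x[i, ] <- flatten_features(window_features(record$data[, idx, drop = FALSE],
                                               fs = record$fs))
  }
  list(x = x, y = lab$label, start_s = lab$start_s,
       patient_id = record$patient_id)
}
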