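# Signal chain: zero-phase Butterworth filtering, resampling to 256 Hz,
# 64 s / 32 s sliding-window segmentation, STFT spectrograms and window
# labelling.

zero_phase <- function(filt, x) as.numeric(signal::filtfilt(filt, x))

#' Apply the standard EEG filter chain
#'
#' A 1 Hz high-pass removes drift and DC, and band-stop filters remove the
#' 60-65 Hz and 120-125 Hz ranges (power-line interference and its image).
#' All filters are 4th-order Butterworth designs applied forward-backward
#' (zero phase), so window labels incur no group delay. Stop bands whose
#' upper edge reaches Nyquist are skipped with a warning.
#'
#' @param record an [eeg_record()] with `fs` > 2 Hz.
#' @return a filtered record of identical shape.
#' @export
apply_filters <- function(record) {
  fs <- record$fs
  if (fs <= 2) stop("apply_filters requires fs > 2 Hz", call. = FALSE)
  nyq <- fs / 2
  hp <- signal::butter(4, 1 / nyq, type = "high")
  stops <- list(c(60, 65), c(120, 125))
  filts <- list(hp)
  for (band in stops) {
    if (band[2] < nyq) {
      filts <- c(filts, list(signal::butter(4, band / nyq, type = "stop")))
    } else {
      warning(sprintf("fs = %g Hz: %g-%g Hz stop band at or above Nyquist, skipped",
                      fs, band[1], band[2]), call. = FALSE)
    }
  }
  out <- record
  for (ch in seq_len(nrow(record$data))) {
    x <- record$data[ch, ]
    for (f in filts) x <- zero_phase(f, x)
    out$data[ch, ] <- x
  }
  out
}

#' Resample a record to 256 Hz
#'
#' Records already at 256 Hz are returned unchanged. Higher-rate recordings
#' are band-passed to 1-100 Hz and rationally resampled to exactly 256 Hz;
#' the duration is preserved to within one sample.
#'
#' @param record an [eeg_record()] with `fs` > 200 Hz.
#' @return the record at 256 Hz.
#' @export
resample_to_256 <- function(record) {
  fs <- record$fs
  if (fs <= 200) {
    stop(sprintf("unsupported sampling rate %g Hz: resample_to_256 requires fs > 200",
                 fs), call. = FALSE)
  }
  if (fs == 256) return(record)
  bp <- signal::butter(4, c(1, 100) / (fs / 2), type = "pass")
  frac <- .rational_ratio(256 / fs)
  n_out <- round(ncol(record$data) * 256 / fs)
  data <- matrix(0, nrow(record$data), n_out)
  for (ch in seq_len(nrow(record$data))) {
    x <- zero_phase(bp, record$data[ch, ])
    y <- signal::resample(x, frac[1], frac[2])
    if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
    data[ch, ] <- y[seq_len(n_out)]
  }
  out <- record
  out$data <- data
  out$fs <- 256
  out
}

# Smallest integer p/q approximation of a rate ratio.
.rational_ratio <- function(r, max_den = 4096) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio as a small rational", call. = FALSE)
}

#' Sliding-window start times
#'
#' Windows are half-open `[start, start + window_s)` on a fixed grid
#' `0, step_s, 2*step_s, ...`; a record shorter than one window yields an
#' empty vector.
#'
#' @param record an [eeg_record()].
#' @param window_s window length in seconds (default 64).
#' @param step_s sliding step in seconds (default 32).
#' @return numeric vector of start times in seconds.
#' @export
segment_windows <- function(record, window_s = 64, step_s = 32) {
  dur <- record_duration(record)
  if (dur < window_s) {
    message(sprintf("record of %.1f s is shorter than one %g s window", dur, window_s))
    return(numeric(0))
  }
  seq(0, dur - window_s, by = step_s)
}

#' STFT configuration
#'
#' @param fs sampling rate in Hz.
#' @param window_s outer analysis window in seconds.
#' @param step_s outer sliding step in seconds.
#' @param segment_len inner STFT segment length in samples (default 256, i.e.
#'   1 s at 256 Hz, giving 1 Hz frequency resolution).
#' @param overlap overlap between consecutive inner segments in samples.
#' @param taper analysis-window family; only `"hann"` is provided.
#' @return an `stft_config` list.
#' @export
stft_config <- function(fs = 256, window_s = 64, step_s = 32,
                        segment_len = 256, overlap = 128, taper = "hann") {
  stopifnot(window_s > step_s, step_s > 0, segment_len <= window_s * fs,
            overlap < segment_len)
  structure(list(fs = fs, window_s = window_s, step_s = step_s,
                 segment_len = segment_len, overlap = overlap, taper = taper),
            class = "stft_config")
}

stft_taper <- function(cfg) {
  if (cfg$taper != "hann") stop("unsupported taper: ", cfg$taper, call. = FALSE)
  n <- cfg$segment_len
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Magnitude spectrogram of one multichannel window
#'
#' Short-time Fourier transform of each channel: the signal is cut into
#' tapered segments of `segment_len` samples advancing by
#' `segment_len - overlap`, each segment is Fourier transformed, and one-sided
#' magnitudes are returned. The transform is linear in the input amplitude.
#'
#' @param x numeric matrix, channels x samples (or a vector for one channel),
#'   of length `window_s * fs` samples.
#' @param cfg an [stft_config()].
#' @return a `spectrogram` list with `magnitudes`
#'   (channels x freq_bins x time_frames, non-negative), `freq_axis` (Hz) and
#'   `time_axis` (segment-centre seconds).
#' @export
stft_spectrogram <- function(x, cfg = stft_config()) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("window contains non-finite samples", call. = FALSE)
  n <- ncol(x)
  if (n != cfg$window_s * cfg$fs) {
    stop(sprintf("window must hold %g samples, got %d", cfg$window_s * cfg$fs, n),
         call. = FALSE)
  }
  len <- cfg$segment_len
  hop <- len - cfg$overlap
  n_frames <- (n - len) %/% hop + 1L
  n_bins <- len %/% 2 + 1L
  h <- stft_taper(cfg)
  mags <- array(0, c(nrow(x), n_bins, n_frames))
  for (fr in seq_len(n_frames)) {
    idx <- (fr - 1L) * hop + seq_len(len)
    seg <- x[, idx, drop = FALSE] * rep(h, each = nrow(x))
    sp <- stats::mvfft(t(seg))
    mags[, , fr] <- t(Mod(sp[seq_len(n_bins), , drop = FALSE]))
  }
  structure(list(magnitudes = mags,
                 freq_axis = (seq_len(n_bins) - 1L) * cfg$fs / len,
                 time_axis = ((seq_len(n_frames) - 1L) * hop + len / 2) / cfg$fs),
            class = "spectrogram")
}

#' Label sliding windows as preictal or interictal
#'
#' A window is labelled preictal (1) when it lies entirely inside the
#' preictal horizon `[onset - preictal_horizon_s, onset)` of some seizure;
#' interictal (0) when its whole span is at least `min_interictal_gap_s`
#' away from every seizure's ictal span. Windows overlapping an ictal span,
#' straddling the horizon boundary, or falling in neither zone are excluded;
#' exclusion counts are attached as the `"excluded"` attribute.
#'
#' @param starts window start times in seconds (see [segment_windows()]).
#' @param annotations sorted seizure annotation table.
#' @param preictal_horizon_s preictal horizon in seconds (default 1200).
#' @param min_interictal_gap_s interictal guard gap in seconds (default 3600).
#' @param window_s window length in seconds.
#' @return data frame with columns `start_s` and `label` (0/1).
#' @export
label_windows <- function(starts, annotations, preictal_horizon_s = 1200,
                          min_interictal_gap_s = 3600, window_s = 64) {
  validate_annotations(annotations)
  ons <- annotations$onset_s; offs <- annotations$offset_s
  lab <- rep(NA_integer_, length(starts))
  n_ictal <- n_neither <- 0L
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + window_s
    if (length(ons) == 0) { lab[i] <- 0L; next }
    if (any(s < offs & e > ons)) { n_ictal <- n_ictal + 1L; next }
    # end strictly before onset, whole window inside the horizon (windows
    # straddling the horizon boundary are excluded, not label-ambiguous)
    pre <- any(e < ons & e >= ons - preictal_horizon_s & s >= ons - preictal_horizon_s)
    inter <- all(e + min_interictal_gap_s <= ons | s >= offs + min_interictal_gap_s)
    if (pre) lab[i] <- 1L
    else if (inter) lab[i] <- 0L
    else n_neither <- n_neither + 1L
  }
  keep <- !is.na(lab)
  out <- data.frame(start_s = starts[keep], label = lab[keep])
  attr(out, "excluded") <- c(ictal = n_ictal, guard_zone = n_neither)
  out
}
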