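# Seeded synthetic-EEG cohorts with planted preictal signatures.
#
# Background model: 1/f^beta coloured noise per channel, a 10 Hz alpha
# oscillator, and a power-line tone at -20 dB relative to the background (so
# the preprocessing band-stop filter has something to remove). Preictal
# minutes preceding each seizure carry the signature the classifier is meant
# to detect: a multiplicative power gain in the theta/alpha range (4-12 Hz)
# and a configurable fraction of shared-source mixing that raises
# inter-channel synchronisation. Seizures themselves appear as short
# high-amplitude 3 Hz spike-wave surrogate bursts and are annotated.

#' Configuration for the synthetic EEG generator
#'
#' Defaults encode the emulated recording conditions: 23-channel scalp EEG at
#' 256 Hz, a 20-minute preictal horizon, a 4-fold preictal theta/alpha power
#' gain with 50% shared-source mixing, 60 Hz line interference over a 1/f
#' background, and base seed 8.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz.
#' @param duration_s record duration in seconds.
#' @param seizure_onsets_s seizure onset times in seconds; each onset plus the
#'   ictal burst must fit inside the record.
#' @param preictal_len_s length of the preictal period before each onset that
#'   carries the planted signature, in seconds.
#' @param theta_alpha_gain multiplicative power gain (>= 1) applied to the
#'   4-12 Hz content of preictal segments; 1 plants no effect.
#' @param sync_gain fraction in \[0, 1\] of shared-source mixing added to
#'   preictal segments; 1 makes all channels copies of one source.
#' @param line_freq power-line frequency in Hz.
#' @param noise_exponent spectral slope beta of the 1/f^beta background.
#' @param seed integer RNG seed; identical configurations are bit-identical.
#' @param seizure_dur_s ictal burst duration in seconds.
#' @param background_rms background RMS amplitude in microvolts.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_channels = 23, fs = 256, duration_s = 3600,
                         seizure_onsets_s = numeric(0), preictal_len_s = 1200,
                         theta_alpha_gain = 4, sync_gain = 0.5,
                         line_freq = 60, noise_exponent = 1, seed = 8,
                         seizure_dur_s = 5, background_rms = 30) {
  cfg <- list(n_channels = n_channels, fs = fs, duration_s = duration_s,
              seizure_onsets_s = sort(as.numeric(seizure_onsets_s)),
              preictal_len_s = preictal_len_s,
              theta_alpha_gain = theta_alpha_gain, sync_gain = sync_gain,
              line_freq = line_freq, noise_exponent = noise_exponent,
              seed = as.integer(seed), seizure_dur_s = seizure_dur_s,
              background_rms = background_rms)
  if (cfg$theta_alpha_gain < 1) stop("theta_alpha_gain must be >= 1", call. = FALSE)
  if (cfg$sync_gain < 0 || cfg$sync_gain > 1) stop("sync_gain must lie in [0, 1]", call. = FALSE)
  if (length(cfg$seizure_onsets_s) &&
      any(cfg$seizure_onsets_s + cfg$seizure_dur_s > cfg$duration_s)) {
    stop("seizure onset beyond record duration", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# Unit-RMS 1/f^beta noise of length n at rate fs, drawn from the current RNG.
coloured_noise <- function(n, fs, beta) {
  n_half <- n %/% 2
  f <- seq_len(n_half) * fs / n
  amp <- f^(-beta / 2)
  z <- complex(real = stats::rnorm(n_half), imaginary = stats::rnorm(n_half)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(n_half + 1)] <- z
  if (n %% 2 == 0) spec[n_half + 1] <- complex(real = Re(spec[n_half + 1]))
  spec[n - seq_len(n - n_half - 1) + 1] <- Conj(spec[2:(n - n_half)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Scale the 4-12 Hz content of a segment so its band power is multiplied by
# `gain`: y = x + (sqrt(gain) - 1) * bandpass(x).
boost_theta_alpha <- function(x, fs, gain) {
  if (gain == 1) return(x)
  bp <- signal::butter(4, c(4, 12) / (fs / 2), type = "pass")
  x + (sqrt(gain) - 1) * signal::filtfilt(bp, x)
}

#' Generate one synthetic EEG record
#'
#' @param cfg a [synth_config()].
#' @return an [eeg_record()] with annotations at the configured onsets.
#' @export
generate_record <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs
  rms <- cfg$background_rms

  shared <- coloured_noise(n, cfg$fs, cfg$noise_exponent) * rms
  line <- sqrt(2) * 0.1 * rms * sin(2 * pi * cfg$line_freq * tt +
                                      stats::runif(1, 0, 2 * pi))
  burst_shape <- function(len_s) {
    tb <- seq_len(round(len_s * cfg$fs)) / cfg$fs
    env <- sin(pi * tb / len_s)^2
    3 * rms * env * (sin(2 * pi * 3 * tb) + 0.5 * sin(2 * pi * 6 * tb))
  }

  pre_idx <- lapply(cfg$seizure_onsets_s, function(on) {
    lo <- max(0, on - cfg$preictal_len_s)
    seq.int(floor(lo * cfg$fs) + 1L, floor(on * cfg$fs))
  })

  data <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    noise <- coloured_noise(n, cfg$fs, cfg$noise_exponent) * rms
    alpha <- 0.3 * rms * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
    for (idx in pre_idx) {
      noise[idx] <- sqrt(1 - cfg$sync_gain) * noise[idx] +
        sqrt(cfg$sync_gain) * shared[idx]
    }
    x <- noise + alpha + line
    # the theta/alpha gain multiplies the whole 4-12 Hz content of the
    # preictal segment (background and alpha rhythm alike)
    for (idx in pre_idx) {
      x[idx] <- boost_theta_alpha(x[idx], cfg$fs, cfg$theta_alpha_gain)
    }
    for (on in cfg$seizure_onsets_s) {
      idx <- floor(on * cfg$fs) + seq_len(round(cfg$seizure_dur_s * cfg$fs))
      x[idx] <- x[idx] + burst_shape(cfg$seizure_dur_s) * stats::runif(1, 0.8, 1.2)
    }
    data[ch, ] <- x
  }

  ann <- seizure_annotations(cfg$seizure_onsets_s,
                             cfg$seizure_onsets_s + cfg$seizure_dur_s)
  eeg_record(data, fs = cfg$fs,
             channel_labels = sprintf("SYN%02d", seq_len(cfg$n_channels)),
             patient_id = "SYN", annotations = ann)
}

#' Generate a synthetic patient cohort on disk
#'
#' Writes one EDF file and one CSV annotation file per synthetic patient,
#' with per-patient seeds derived deterministically from the base seed
#' (base seed + patient index), plus a JSON manifest listing the files.
#'
#' @param n_patients number of patients (>= 1).
#' @param base_cfg a [synth_config()] shared by all patients except for the
#'   derived seed and patient id.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a data frame with columns `patient_id`, `edf`,
#'   `annotations`, `seed` (paths relative to `out_dir`), invisibly also
#'   written to `manifest.json`.
#' @export
generate_cohort <- function(n_patients, base_cfg, out_dir) {
  stopifnot(n_patients >= 1, inherits(base_cfg, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  entries <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pid <- sprintf("S%02d", i)
    cfg_i <- base_cfg
    cfg_i$seed <- base_cfg$seed + i
    rec <- generate_record(cfg_i)
    rec$patient_id <- pid
    edf_name <- paste0(pid, ".edf")
    ann_name <- paste0(pid, "_seizures.csv")
    write_edf(rec, file.path(out_dir, edf_name))
    write_annotations(rec$annotations, file.path(out_dir, ann_name))
    entries[[i]] <- data.frame(patient_id = pid, edf = edf_name,
                               annotations = ann_name, seed = cfg_i$seed)
  }
  manifest <- do.call(rbind, entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE, digits = NA)
  manifest
}
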