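rms_db <- function(a, b) 10 * log10(mean(a^2) / mean(b^2))
trim_idx <- function(n, fs, s = 2) (s * fs):(n - s * fs)

test_that("filter chain attenuates stop bands and preserves the pass band", {
  fs <- 256
  tone <- function(f) sine_record(f, fs = fs, dur = 20)
  for (f_stop in c(62, 122)) {
    rec <- tone(f_stop)
    out <- apply_filters(rec)
    i <- trim_idx(ncol(rec$data), fs)
    expect_lt(rms_db(out$data[1, i], rec$data[1, i]), -20)
  }
  rec10 <- tone(10)
  out10 <- apply_filters(rec10)
  i <- trim_idx(ncol(rec10$data), fs)
  expect_lt(abs(rms_db(out10$data[1, i], rec10$data[1, i])), 1)
})

test_that("high-pass removes DC and the chain is order-stable", {
  fs <- 256
  dc <- eeg_record(matrix(5, 1, fs * 20), fs = fs)
  out <- apply_filters(dc)
  i <- trim_idx(fs * 20, fs)
  expect_lt(abs(mean(out$data[1, i])), 1e-3)

  rec10 <- sine_record(10, dur = 20)
  once <- apply_filters(rec10)
  twice <- apply_filters(once)
  i <- trim_idx(ncol(rec10$data), fs)
  expect_lt(abs(rms_db(twice$data[1, i], once$data[1, i])), 0.5)
})

test_that("filters warn when a stop band reaches Nyquist and reject fs <= 2", {
  rec <- eeg_record(matrix(rnorm(210 * 10), 1), fs = 210)
  expect_warning(apply_filters(rec), "120-125")
  expect_error(apply_filters(eeg_record(matrix(rnorm(10), 1), fs = 2)),
               "fs > 2")
})

test_that("resampling reaches exactly 256 Hz and preserves tones", {
  rec256 <- sine_record(10, fs = 256, dur = 4)
  expect_identical(resample_to_256(rec256), rec256)

  rec512 <- sine_record(10, fs = 512, dur = 10)
  out <- resample_to_256(rec512)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), 2560)     # 10 s x 256 Hz
  pg <- stats::spec.pgram(stats::ts(out$data[1, ], frequency = 256), plot = FALSE)
  expect_equal(pg$freq[which.max(pg$spec)], 10, tolerance = 0.05)

  expect_error(resample_to_256(eeg_record(matrix(rnorm(400), 1), fs = 128)),
               "unsupported")
})

test_that("segmentation start grid and count follow the 64/32 rule", {
  mk <- function(dur) eeg_record(matrix(0, 1, dur * 256), fs = 256)
  expect_equal(segment_windows(mk(64)), 0)
  expect_equal(segment_windows(mk(96)), c(0, 32))
  expect_length(suppressMessages(segment_windows(mk(63))), 0)
  # exhaustive, non-redundant: consecutive windows overlap by exactly 32 s
  st <- segment_windows(mk(1000))
  expect_equal(length(st), floor((1000 - 64) / 32) + 1)
  expect_true(all(diff(st) == 32))
})

test_that("STFT is linear, peaks at the tone frequency and conserves energy", {
  fs <- 256
  zero <- stft_spectrogram(matrix(0, 1, 64 * fs))
  expect_true(all(zero$magnitudes == 0))
  expect_equal(dim(zero$magnitudes)[2], 256 / 2 + 1)  # segment_len/2 + 1 bins

  w <- sin(2 * pi * 10 * seq_len(64 * fs) / fs)
  sp <- stft_spectrogram(matrix(w, 1))
  peaks <- sp$freq_axis[apply(sp$magnitudes[1, , ], 2, which.max)]
  expect_true(all(peaks == 10))

  sp2 <- stft_spectrogram(matrix(2 * w, 1))
  expect_equal(sp2$magnitudes, 2 * sp$magnitudes, tolerance = 1e-9)

  expect_error(stft_spectrogram(matrix(NA_real_, 1, 64 * fs)), "non-finite")
  expect_error(stft_spectrogram(matrix(0, 1, 100)), "samples")

  # Parseval-style energy consistency for white noise
  set.seed(5)
  x <- rnorm(64 * fs)
  cfg <- stft_config()
  sp3 <- stft_spectrogram(matrix(x, 1), cfg)
  m <- sp3$magnitudes[1, , ]
  one_sided <- m^2
  one_sided[2:128, ] <- 2 * one_sided[2:128, ]       # double non-DC/non-Nyquist
  e_spec <- sum(one_sided) / cfg$segment_len
  h <- cgtnet:::stft_taper(cfg)
  hop <- cfg$segment_len - cfg$overlap
  e_win <- sum(vapply(seq_len(dim(m)[2]), function(fr) {
    sum((x[(fr - 1) * hop + seq_len(cfg$segment_len)] * h)^2)
  }, 0))
  expect_lt(abs(e_spec - e_win) / e_win, 0.05)
})

test_that("window labelling follows the horizon, guard-gap and ictal rules", {
  ann <- seizure_annotations(5000, 5030)
  # ends 600 s before onset -> preictal
  lab <- label_windows(4336, ann)
  expect_equal(lab$label, 1)
  # 2 h away from the seizure -> interictal
  expect_equal(label_windows(12000, ann)$label, 0)
  # overlapping the ictal span -> excluded
  out <- label_windows(4990, ann)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "excluded")[["ictal"]], 1)
  # straddling the horizon boundary (onset - 1200 = 3800) -> excluded
  expect_equal(nrow(label_windows(3790, ann)), 0)
  # inside the guard gap but not preictal -> excluded
  expect_equal(nrow(label_windows(2000, ann)), 0)
  # no seizures at all -> everything interictal
  expect_equal(label_windows(c(0, 32), seizure_annotations())$label, c(0, 0))
})
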