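# The generator's contracts: determinism, the planted theta/alpha power
# signature (checked against an independent periodogram oracle), the
# synchronisation invariant and annotation placement.

test_that("identical configuration and seed give bit-identical records", {
  cfg <- synth_config(n_channels = 3, duration_s = 300, seed = 8)
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$annotations, b$annotations)
})

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(theta_alpha_gain = 0.5), "theta_alpha_gain")
  expect_error(synth_config(sync_gain = 1.2), "sync_gain")
  expect_error(synth_config(duration_s = 100, seizure_onsets_s = 99),
               "beyond record duration")
})

test_that("no planted effect means matching preictal/interictal band power", {
  cfg <- synth_config(n_channels = 2, duration_s = 2400, seizure_onsets_s = 2000,
                      theta_alpha_gain = 1, sync_gain = 0, seed = 8)
  rec <- generate_record(cfg)
  pre <- rec$data[1, (800 * 256 + 1):(2000 * 256)]
  inter <- rec$data[1, 1:(800 * 256)]
  ratio <- welch_band_power(pre, 256, 4, 12) /
    welch_band_power(inter, 256, 4, 12)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("theta/alpha gain 4 at least doubles 4-12 Hz preictal band power", {
  cfg <- synth_config(n_channels = 2, duration_s = 2400, seizure_onsets_s = 2000,
                      theta_alpha_gain = 4, seed = 8)
  rec <- generate_record(cfg)
  for (ch in 1:2) {
    ratio <- welch_band_power(rec$data[ch, (800 * 256 + 1):(2000 * 256)], 256, 4, 12) /
      welch_band_power(rec$data[ch, 1:(800 * 256)], 256, 4, 12)
    expect_gte(ratio, 2)
  }
})

test_that("the planted band-power ratio increases strictly with the gain", {
  ratios <- vapply(c(1, 2, 4, 8), function(g) {
    cfg <- synth_config(n_channels = 1, duration_s = 2400,
                        seizure_onsets_s = 2000, theta_alpha_gain = g,
                        sync_gain = 0.5, seed = 8)
    rec <- generate_record(cfg)
    welch_band_power(rec$data[1, (800 * 256 + 1):(2000 * 256)], 256, 4, 12) /
      welch_band_power(rec$data[1, 1:(800 * 256)], 256, 4, 12)
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("full sync makes preictal channels near-copies of one source", {
  cfg <- synth_config(n_channels = 6, duration_s = 1800, seizure_onsets_s = 1500,
                      sync_gain = 1, seed = 8)
  rec <- generate_record(cfg)
  seg <- rec$data[, (300 * 256 + 1):(1500 * 256)]
  cc <- stats::cor(t(seg))
  expect_gte(mean(cc[upper.tri(cc)]), 0.8)
})

test_that("signals are finite and zero-mean after the 1 Hz high-pass", {
  cfg <- synth_config(n_channels = 3, duration_s = 600, seizure_onsets_s = 500,
                      seed = 8)
  rec <- generate_record(cfg)
  expect_true(all(is.finite(rec$data)))
  filt <- apply_filters(rec)
  trim <- (2 * 256):(ncol(filt$data) - 2 * 256)
  expect_true(all(abs(rowMeans(filt$data[, trim])) < 1))
})

test_that("cohorts are written completely and reproducibly", {
  base <- synth_config(n_channels = 2, duration_s = 600,
                       seizure_onsets_s = c(200, 500), preictal_len_s = 100,
                       seed = 8)
  d1 <- withr::local_tempdir()
  man <- generate_cohort(3, base, d1)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(file.path(d1, man$edf))))
  expect_true(all(file.exists(file.path(d1, man$annotations))))
  # each patient carries exactly the configured seizures
  for (i in 1:3) {
    ann <- read_annotations(file.path(d1, man$annotations[i]))
    expect_equal(ann$onset_s, c(200, 500))
  }
  # derived seeds and byte-identical manifests across runs
  expect_equal(man$seed, 8 + 1:3)
  d2 <- withr::local_tempdir()
  generate_cohort(3, base, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
})
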