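test_that("QRS detection is exact on noise-free fixtures of every rhythm class", {
  for (cls in RHYTHM_CLASSES) {
    rec <- make_record(cls, mean_hr = if (is_af_rhythm(cls)) 90 else 62,
                       seed = 11)
    pk <- detect_qrs(remove_baseline(rec))
    m <- match_peaks(pk, rec$truth$r_peaks, tol = 0.02)
    expect_equal(m$precision, 1.0, info = cls)
    expect_equal(m$recall, 1.0, info = cls)
  }
})

test_that("detection works on low-voltage and slow/fast sinus fixtures", {
  for (fix in list(list(hr = 45, qrs = 1.0), list(hr = 110, qrs = 1.0),
                   list(hr = 62, qrs = 0.4))) {
    rec <- make_record("SINUS", fix$hr, seed = 12,
                       wf = waveform_params(qrs_amplitude = fix$qrs))
    pk <- detect_qrs(remove_baseline(rec))
    m <- match_peaks(pk, rec$truth$r_peaks, tol = 0.02)
    expect_equal(m$precision, 1.0)
    expect_equal(m$recall, 1.0)
  }
})

test_that("an all-zero signal yields an empty peak list", {
  expect_length(detect_qrs(ecg_record(rep(0, 7500), fs = 500)), 0)
})

test_that("detected peak times are strictly increasing with a 200 ms refractory", {
  rec <- make_record("AF", 110, seed = 31)
  pk <- detect_qrs(remove_baseline(rec))
  expect_true(all(diff(pk) >= 0.2))
})

test_that("RR statistics match direct arithmetic", {
  expect_equal(rr_statistics(c(1, 1, 1, 1)),
               list(rr_cv = 0, rr_rmssd_norm = 0, pct_delta_rr_gt = 0))
  st <- rr_statistics(c(0.6, 1.0, 0.6, 1.0))
  expect_equal(st$rr_cv, sd(c(0.6, 1, 0.6, 1)) / 0.8)
  expect_equal(round(st$rr_cv, 4), 0.2887)
  expect_equal(st$rr_rmssd_norm, 0.4 / 0.8)
  expect_equal(st$pct_delta_rr_gt, 1)
  expect_error(rr_statistics(c(1, 1)), class = "afscreen_insufficient_beats")
})

test_that("RR irregularity measures are scale-invariant", {
  rr <- generate_rr_sequence(rhythm_spec("AF", mean_hr = 90, seed = 5), 15)
  a <- rr_statistics(rr)
  b <- rr_statistics(2.5 * as.numeric(rr))
  expect_equal(a$rr_cv, b$rr_cv, tolerance = 1e-12)
  expect_equal(a$rr_rmssd_norm, b$rr_rmssd_norm, tolerance = 1e-12)
})

test_that("P-wave score separates sinus, AF and junctional fixtures", {
  sinus <- make_filtered("SINUS", 62, seed = 13,
                         wf = waveform_params(p_amplitude = 0.15),
                         noise = noise_spec(broadband_noise_sd = 0.01, seed = 14))
  pk <- detect_qrs(sinus)
  expect_gte(p_wave_score(sinus, pk), 0.8)

  af <- make_filtered("AF", 90, seed = 13)
  expect_lte(p_wave_score(af, detect_qrs(af)), 0.3)

  junc <- make_filtered("JUNCTIONAL", 55, seed = 13)
  expect_lte(p_wave_score(junc, detect_qrs(junc)), 0.3)

  expect_error(p_wave_score(sinus, pk[1:2]),
               class = "afscreen_insufficient_beats")
})

test_that("P-wave score is monotone in the generated P amplitude", {
  scores <- vapply(c(0, 0.04, 0.08, 0.15), function(a) {
    rec <- make_filtered("SINUS", 62, seed = 17,
                         wf = waveform_params(p_amplitude = a))
    p_wave_score(rec, detect_qrs(rec))
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_lte(scores[1], 0.1)
  expect_gte(scores[4], 0.8)
})

test_that("QRS amplitude recovers the generated voltage", {
  rec <- make_filtered("SINUS", 62, seed = 19,
                       wf = waveform_params(qrs_amplitude = 1.0))
  pk <- detect_qrs(rec)
  amp <- qrs_amplitude(rec, pk)
  expect_gte(amp, 0.9)
  expect_lte(amp, 1.1)

  low <- make_filtered("SINUS", 62, seed = 19,
                       wf = waveform_params(qrs_amplitude = 0.4))
  expect_lt(qrs_amplitude(low, detect_qrs(low)), 0.5)

  expect_error(qrs_amplitude(rec, numeric(0)),
               class = "afscreen_insufficient_beats")
})

test_that("extract_features flags records that cannot be auto-classified", {
  flat <- ecg_record(rep(0, 7500), fs = 500)
  feats <- extract_features(flat)
  expect_true(feats$insufficient)
  expect_identical(feats$n_beats, 0L)
  expect_true(is.na(feats$rr_cv))
})
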