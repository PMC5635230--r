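test_that("sinus RR sequences are low-variability and cover the duration", {
  rr <- generate_rr_sequence(rhythm_spec("SINUS", mean_hr = 60, rr_cv = 0.03,
                                         seed = 42), 15)
  expect_gte(length(rr), 14)
  expect_lte(length(rr), 16)
  expect_lte(sd(rr) / mean(rr), 0.05)
  expect_gte(sum(rr), 15 - max(rr))
  expect_true(all(rr >= 0.3 & rr <= 2.0))
})

test_that("AF RR sequences are irregular by construction", {
  # oracle: direct computation of the sample CV on the drawn sequence
  for (seed in c(7, 19, 33)) {
    rr <- generate_rr_sequence(rhythm_spec("AF", mean_hr = 90, seed = seed), 15)
    expect_gte(sd(rr) / mean(rr), 0.15)
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_rr_sequence(rhythm_spec("SINUS"), 0),
               class = "afscreen_invalid_parameter")
  expect_error(rhythm_spec("SINUS", mean_hr = 10),
               class = "afscreen_invalid_parameter")
  expect_error(rhythm_spec("SINUS", rr_cv = -1),
               class = "afscreen_invalid_parameter")
  expect_error(noise_spec(corrupted_fraction = 1.5),
               class = "afscreen_invalid_parameter")
  expect_error(synthesize_ecg(numeric(0), waveform_params()),
               class = "afscreen_invalid_parameter")
  expect_error(synthesize_ecg(rep(1, 10), waveform_params(), fs = 60),
               class = "afscreen_invalid_parameter")
})

test_that("rendered records have the exact sample count and truth R peaks", {
  rr <- generate_rr_sequence(rhythm_spec("SINUS", mean_hr = 60, seed = 1), 15)
  rec <- synthesize_ecg(rr, waveform_params(), fs = 500)
  expect_identical(length(rec$samples), 7500L)
  r_expected <- 0.35 + c(0, cumsum(rr))
  r_expected <- r_expected[r_expected <= 15 - 0.12]
  expect_equal(rec$truth$r_peaks, r_expected)
  # sample-count invariant across rates and durations
  for (fs in c(250, 360, 500)) {
    rec2 <- synthesize_ecg(rr, waveform_params(), fs = fs, duration = 15)
    expect_identical(length(rec2$samples), as.integer(round(fs * 15)))
  }
})

test_that("identical seeds give identical waveforms", {
  a <- make_record("AF", 90, seed = 5,
                   noise = noise_spec(broadband_noise_sd = 0.02, seed = 9))
  b <- make_record("AF", 90, seed = 5,
                   noise = noise_spec(broadband_noise_sd = 0.02, seed = 9))
  expect_identical(a$samples, b$samples)
})

test_that("AF records carry f waves but no P waves before the QRS", {
  wf <- waveform_params(f_wave_amplitude = 0.1)
  rec <- make_record("AF", 90, seed = 7, wf = wf)
  # mean absolute amplitude in the windows preceding each R peak stays at
  # the fibrillatory-wave scale (no broadband noise here)
  means <- vapply(rec$truth$r_peaks, function(r) {
    if (r < 0.26) return(NA_real_)
    idx <- (floor((r - 0.25) * 500) + 1):(floor((r - 0.08) * 500) + 1)
    mean(abs(rec$samples[idx]))
  }, numeric(1))
  expect_lte(mean(means, na.rm = TRUE), wf$f_wave_amplitude)
})

test_that("low-voltage mode renders QRS peaks below 0.5 mV", {
  rec <- make_record("SINUS", 62, seed = 3,
                     wf = waveform_params(qrs_amplitude = 0.4))
  expect_lt(max(rec$samples), 0.5)
})

test_that("ectopy truth matches the number of inserted premature beats", {
  for (cls in c("SINUS_APC", "SINUS_VPC", "SINUS_APC_VPC")) {
    spec <- rhythm_spec(cls, mean_hr = 62, seed = 11)
    rr <- generate_rr_sequence(spec, 15)
    rec <- synthesize_ecg(rr, waveform_params())
    expect_identical(rec$truth$n_ectopic, nrow(attr(rr, "ectopy")))
    expect_identical(rec$truth$n_ectopic, as.integer(round(spec$ectopy_rate)))
  }
})

test_that("zero-noise artifact spec is the identity", {
  rec <- make_record(seed = 2)
  out <- add_artifacts(rec, noise_spec())
  expect_identical(out$samples, rec$samples)
})

test_that("burst corruption covers the requested fraction, with truth", {
  rec <- make_record(seed = 2)
  out <- add_artifacts(rec, noise_spec(corrupted_fraction = 0.5, seed = 13))
  iv <- out$truth$corrupted_intervals
  expect_equal(sum(iv[, "end"] - iv[, "start"]), 7.5, tolerance = 1e-9)
})

test_that("baseline wander injects a dominant spectral peak at its frequency", {
  rec <- make_record(seed = 2)
  out <- add_artifacts(rec, noise_spec(baseline_wander_amplitude = 1,
                                       baseline_wander_freq = 0.3, seed = 4))
  d <- out$samples - rec$samples
  sp <- Mod(fft(d))[2:300]
  freqs <- (1:299) * 500 / 7500
  # the peak lands on the DFT bin nearest 0.3 Hz (bin spacing 1/15 Hz)
  expect_lte(abs(freqs[which.max(sp)] - 0.3), 0.04)
})

test_that("cohorts hit stratum prevalence within binomial bounds and are reproducible", {
  spec <- cohort_spec(n_subjects = 500, seed = 99,
                      prevalence_gt65 = 0.042, prevalence_le65 = 0.008)
  coh <- generate_cohort(spec)
  m <- coh$manifest
  first <- m[!duplicated(m$subject_id), ]
  for (s in list(list(sel = first$age > 65, p = 0.042),
                 list(sel = first$age <= 65, p = 0.008))) {
    n <- sum(s$sel)
    k <- sum(first$is_af[s$sel])
    bounds <- qbinom(c(0.025, 0.975), n, s$p)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
  coh2 <- generate_cohort(spec)
  expect_identical(coh$manifest, coh2$manifest)
  # degenerate mix: all sinus, no AF
  spec0 <- cohort_spec(n_subjects = 30, seed = 1, prevalence_gt65 = 0,
                       prevalence_le65 = 0,
                       rhythm_mix_non_af = c(SINUS = 1))
  coh0 <- generate_cohort(spec0)
  expect_true(all(!coh0$manifest$is_af))
  expect_true(all(coh0$manifest$true_rhythm == "SINUS"))
  expect_error(cohort_spec(n_subjects = 0),
               class = "afscreen_invalid_parameter")
})

test_that("ECG CSV round-trips through the interchange format", {
  rec <- make_record(seed = 8, duration = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(rec, path)
  back <- read_ecg_csv(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
})
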