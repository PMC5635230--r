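# Noise injection matching each target artifact grade class. Grade-2 classes
# come in two flavours (burst-dominated vs wander-dominated); grade 3 is an
# electrode-failure proxy: essentially no cardiac signal under continuous
# burst noise.
noise_for_grade <- function(grade_class, seed) {
  switch(grade_class,
    "0" = noise_spec(baseline_wander_amplitude = runif(1, 0, 0.1),
                     baseline_wander_freq = 0.3,
                     broadband_noise_sd = runif(1, 0.005, 0.015), seed = seed),
    "1" = noise_spec(baseline_wander_amplitude = runif(1, 0.05, 0.3),
                     baseline_wander_freq = 0.3,
                     broadband_noise_sd = runif(1, 0.01, 0.025),
                     corrupted_fraction = runif(1, 0.08, 0.28), seed = seed),
    "2a" = if (runif(1) < 0.7) {
      noise_spec(broadband_noise_sd = runif(1, 0.01, 0.03),
                 corrupted_fraction = runif(1, 0.36, 0.62), seed = seed)
    } else {
      noise_spec(baseline_wander_amplitude = runif(1, 0.7, 1.3),
                 baseline_wander_freq = 0.45,
                 broadband_noise_sd = runif(1, 0.01, 0.03),
                 corrupted_fraction = runif(1, 0.08, 0.25), seed = seed)
    },
    "2b" = if (runif(1) < 0.7) {
      noise_spec(broadband_noise_sd = runif(1, 0.01, 0.03),
                 corrupted_fraction = runif(1, 0.70, 0.92), seed = seed)
    } else {
      noise_spec(baseline_wander_amplitude = runif(1, 2.5, 4),
                 baseline_wander_freq = 0.45,
                 broadband_noise_sd = runif(1, 0.01, 0.03),
                 corrupted_fraction = runif(1, 0.2, 0.4), seed = seed)
    },
    "3" = noise_spec(broadband_noise_sd = 0.05, corrupted_fraction = 1,
                     burst_noise_sd = 0.6, seed = seed)
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic screening cohort
#'
#' Draws subjects (age, sex, subject-level AF status by age-stratum
#' prevalence, rhythm class), the number of recordings per subject, and a
#' target artifact grade class per recording, then synthesizes every record
#' through [generate_rr_sequence()], [synthesize_ecg()] and
#' [add_artifacts()]. The whole cohort is reproducible from the master seed;
#' every record additionally carries its own sub-seed in the manifest.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (list of [ecg_record()]) and `manifest`
#'   (data frame: `record_id, subject_id, age, sex, true_rhythm, is_af,
#'   grade_class, seed, mean_hr, qrs_amplitude`).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_invalid("`spec` must be a cohort_spec")
  withr::with_seed(as.integer(spec$seed), {
    ns <- spec$n_subjects
    age <- round(rtrunc_norm(ns, spec$age_mean, spec$age_sd,
                             spec$age_min, spec$age_max))
    sex <- ifelse(runif(ns) < spec$male_fraction, "M", "F")
    prev <- ifelse(age > 65, spec$prevalence_gt65, spec$prevalence_le65)
    af <- runif(ns) < prev
    rhythm <- character(ns)
    rhythm[af] <- ifelse(runif(sum(af)) < spec$af_vpc_fraction, "AF_VPC", "AF")
    rhythm[!af] <- sample(names(spec$rhythm_mix_non_af), sum(!af),
                          replace = TRUE, prob = spec$rhythm_mix_non_af)
    u <- runif(ns)
    n_rec <- ifelse(u < spec$repeat_three, 3L,
                    ifelse(u < spec$repeat_three + spec$repeat_two, 2L, 1L))

    subj_idx <- rep(seq_len(ns), n_rec)
    n_total <- length(subj_idx)
    grade_class <- sample(names(spec$grade_mix), n_total, replace = TRUE,
                          prob = spec$grade_mix)
    sub_seed <- draw_subseeds(2L * n_total)
    mean_hr <- ifelse(af[subj_idx],
                      rtrunc_norm(n_total, 88, 12, 55, 140),
                      rtrunc_norm(n_total, 72, 8, 45, 110))
    low_volt <- runif(n_total) < spec$low_voltage_fraction
    qrs_amp <- ifelse(low_volt, runif(n_total, 0.3, 0.48),
                      runif(n_total, 0.7, 1.4))
    p_amp <- runif(n_total, 0.1, 0.2)

    records <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      s <- subj_idx[i]
      rs <- rhythm_spec(rhythm[s], mean_hr = mean_hr[i], seed = sub_seed[i])
      rr <- generate_rr_sequence(rs, spec$duration)
      wf <- waveform_params(
        p_amplitude = p_amp[i],
        qrs_amplitude = if (grade_class[i] == "3") 0.03 else qrs_amp[i]
      )
      rec <- synthesize_ecg(rr, wf, fs = spec$fs, duration = spec$duration,
                            subject_id = sprintf("S%04d", s), age = age[s])
      rec <- add_artifacts(rec, noise_for_grade(grade_class[i],
                                                sub_seed[n_total + i]))
      rec$truth$grade_class <- grade_class[i]
      records[[i]] <- rec
    }

    manifest <- data.frame(
      record_id = sprintf("R%04d", seq_len(n_total)),
      subject_id = sprintf("S%04d", subj_idx),
      age = age[subj_idx],
      sex = sex[subj_idx],
      true_rhythm = rhythm[subj_idx],
      is_af = af[subj_idx],
      grade_class = grade_class,
      seed = sub_seed[seq_len(n_total)],
      mean_hr = round(mean_hr, 1),
      qrs_amplitude = round(qrs_amp, 3),
      stringsAsFactors = FALSE
    )
    list(records = records, manifest = manifest)
  })
}

#' Subject-level AF counts of a cohort (first recording per resident)
#'
#' @param manifest a cohort manifest.
#' @param age_split age boundary.
#' @return list of `c(af, n)` per stratum (`le`, `gt`, `overall`).
#' @export
resident_counts <- function(manifest, age_split = 65) {
  first <- manifest[!duplicated(manifest$subject_id), ]
  cnt <- function(d) c(sum(d$is_af), nrow(d))
  list(
    le = cnt(first[first$age <= age_split, ]),
    gt = cnt(first[first$age > age_split, ]),
    overall = cnt(first)
  )
}
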