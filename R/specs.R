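#' Rhythm classes known to the generator
#'
#' Sinus rhythm with and without atrial (APC) or ventricular (VPC) premature
#' complexes, atrial fibrillation with and without VPCs, junctional rhythm and
#' paced rhythm -- the taxonomy observed in community AF screening.
#'
#' @export
RHYTHM_CLASSES <- c(
  "SINUS", "SINUS_APC", "SINUS_VPC", "SINUS_APC_VPC",
  "AF", "AF_VPC", "JUNCTIONAL", "PACED"
)

#' Is a rhythm class atrial fibrillation?
#' @param rhythm_class character vector of rhythm class labels.
#' @return logical vector.
#' @export
is_af_rhythm <- function(rhythm_class) rhythm_class %in% c("AF", "AF_VPC")

# Classes with no atrial depolarization visible on the surface lead: the
# rendered P amplitude is forced to zero for these.
p_free_rhythm <- function(rhythm_class) {
  rhythm_class %in% c("AF", "AF_VPC", "JUNCTIONAL", "PACED")
}

default_rr_cv <- function(rhythm_class) {
  switch(rhythm_class,
    AF = 0.24, AF_VPC = 0.24,
    JUNCTIONAL = 0.03, PACED = 0.01,
    0.04
  )
}

default_ectopy_rate <- function(rhythm_class) {
  switch(rhythm_class,
    SINUS_APC = 3, SINUS_VPC = 3, SINUS_APC_VPC = 4, AF_VPC = 2,
    0
  )
}

#' Rhythm generator parameters
#'
#' @param rhythm_class one of [RHYTHM_CLASSES].
#' @param mean_hr mean heart rate in beats/min, in \[30, 220\].
#' @param rr_cv target coefficient of variation of the RR intervals
#'   (dimensionless). Defaults depend on the class: 0.24 for AF (the
#'   irregularly-irregular pattern), 0.04 for sinus, 0.01 for paced.
#' @param ectopy_rate number of ectopic beats inserted per recording
#'   (rounded to an integer count).
#' @param seed optional integer seed making the RR draw reproducible.
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rhythm_class = "SINUS", mean_hr = 70, rr_cv = NULL,
                        ectopy_rate = NULL, seed = NULL) {
  rhythm_class <- match.arg(rhythm_class, RHYTHM_CLASSES)
  assert_scalar_number(mean_hr, "mean_hr", 30, 220)
  rr_cv <- rr_cv %||% default_rr_cv(rhythm_class)
  ectopy_rate <- ectopy_rate %||% default_ectopy_rate(rhythm_class)
  assert_scalar_number(rr_cv, "rr_cv", 0)
  assert_scalar_number(ectopy_rate, "ectopy_rate", 0)
  structure(
    list(rhythm_class = rhythm_class, mean_hr = mean_hr, rr_cv = rr_cv,
         ectopy_rate = ectopy_rate, seed = seed),
    class = "rhythm_spec"
  )
}

#' Beat morphology parameters (sum-of-Gaussians template)
#'
#' Each beat is rendered as parameterized Gaussian waves (P, Q, R, S, T).
#' `qrs_amplitude` is the peak-to-trough QRS voltage the template realizes;
#' a low-voltage recording is expressed as `qrs_amplitude < 0.5` mV. For AF
#' classes the P wave is replaced by a continuous fibrillatory (f) wave at
#' `f_wave_freq` with amplitude `f_wave_amplitude`.
#'
#' @param p_amplitude P-wave amplitude, mV.
#' @param qrs_amplitude QRS peak-to-trough amplitude, mV.
#' @param t_amplitude T-wave amplitude, mV.
#' @param p_width,qrs_width,t_width Gaussian widths (sigma) in seconds.
#' @param f_wave_amplitude fibrillatory-wave amplitude, mV (AF only).
#' @param f_wave_freq fibrillatory-wave frequency, Hz (typically 4--10).
#' @return an object of class `waveform_params`.
#' @export
waveform_params <- function(p_amplitude = 0.15, qrs_amplitude = 1.0,
                            t_amplitude = 0.3, p_width = 0.025,
                            qrs_width = 0.012, t_width = 0.05,
                            f_wave_amplitude = 0.1, f_wave_freq = 6) {
  for (nm in c("p_amplitude", "qrs_amplitude", "t_amplitude",
               "f_wave_amplitude")) {
    assert_scalar_number(get(nm), nm, 0)
  }
  for (nm in c("p_width", "qrs_width", "t_width", "f_wave_freq")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v <= 0) stop_invalid(sprintf("`%s` must be > 0", nm))
  }
  structure(
    list(p_amplitude = p_amplitude, qrs_amplitude = qrs_amplitude,
         t_amplitude = t_amplitude, p_width = p_width, qrs_width = qrs_width,
         t_width = t_width, f_wave_amplitude = f_wave_amplitude,
         f_wave_freq = f_wave_freq),
    class = "waveform_params"
  )
}

# Apply the rhythm-class constraint: no atrial P wave for AF, junctional and
# (ventricular) paced rhythms; f waves only rendered for AF classes.
waveform_for_class <- function(wf, rhythm_class) {
  if (p_free_rhythm(rhythm_class)) wf$p_amplitude <- 0
  if (!is_af_rhythm(rhythm_class)) wf$f_wave_amplitude <- 0
  wf
}

#' Noise and artifact injection parameters
#'
#' @param baseline_wander_amplitude amplitude of the sinusoidal baseline
#'   wander, mV.
#' @param baseline_wander_freq wander frequency in Hz, in (0, 0.5).
#' @param broadband_noise_sd standard deviation of additive Gaussian noise
#'   over the whole recording, mV.
#' @param corrupted_fraction fraction of the recording duration carrying
#'   burst noise, in \[0, 1\].
#' @param burst_noise_sd standard deviation of the burst noise, mV.
#' @param seed optional integer seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_wander_amplitude = 0,
                       baseline_wander_freq = 0.3,
                       broadband_noise_sd = 0,
                       corrupted_fraction = 0,
                       burst_noise_sd = 0.5,
                       seed = NULL) {
  assert_scalar_number(baseline_wander_amplitude, "baseline_wander_amplitude", 0)
  assert_scalar_number(broadband_noise_sd, "broadband_noise_sd", 0)
  assert_scalar_number(burst_noise_sd, "burst_noise_sd", 0)
  assert_scalar_number(corrupted_fraction, "corrupted_fraction", 0, 1)
  assert_scalar_number(baseline_wander_freq, "baseline_wander_freq")
  if (baseline_wander_freq <= 0 || baseline_wander_freq >= 0.5) {
    stop_invalid("`baseline_wander_freq` must lie in (0, 0.5) Hz")
  }
  structure(
    list(baseline_wander_amplitude = baseline_wander_amplitude,
         baseline_wander_freq = baseline_wander_freq,
         broadband_noise_sd = broadband_noise_sd,
         corrupted_fraction = corrupted_fraction,
         burst_noise_sd = burst_noise_sd, seed = seed),
    class = "noise_spec"
  )
}

is_zero_noise <- function(noise) {
  noise$baseline_wander_amplitude == 0 && noise$broadband_noise_sd == 0 &&
    noise$corrupted_fraction == 0
}

#' Cohort simulation parameters
#'
#' Describes a screened community: subject count, age structure, age-specific
#' AF prevalence, the conditional rhythm mix among non-AF subjects, the
#' artifact grade mix, and repeat-recording probabilities. Defaults emulate a
#' community screening population (mean age 58.1, SD 15.0; AF prevalence 4.1%
#' above age 65 and 0.8% at or below; roughly 83.5/12.8/2.7/0.8/0.2% of
#' recordings at artifact grades 0/1/2a/2b/3).
#'
#' @param n_subjects number of screened residents.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @param age_mean,age_sd,age_min,age_max age distribution (normal, truncated).
#' @param prevalence_gt65,prevalence_le65 subject-level AF probability in the
#'   two age strata.
#' @param male_fraction probability a subject is male.
#' @param rhythm_mix_non_af named probabilities over non-AF rhythm classes.
#' @param af_vpc_fraction probability an AF subject also shows VPCs.
#' @param grade_mix named probabilities over artifact grade classes
#'   `c("0","1","2a","2b","3")`.
#' @param low_voltage_fraction fraction of recordings with QRS amplitude drawn
#'   below 0.5 mV (a known false-positive-prone feature).
#' @param repeat_two,repeat_three probability a subject contributes two /
#'   three recordings.
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 500, seed = 20160311,
                        age_mean = 58.1, age_sd = 15.0,
                        age_min = 20, age_max = 95,
                        prevalence_gt65 = 0.041, prevalence_le65 = 0.008,
                        male_fraction = 0.366,
                        rhythm_mix_non_af = c(
                          SINUS = 907, SINUS_APC = 15, SINUS_VPC = 19,
                          SINUS_APC_VPC = 1, JUNCTIONAL = 3, PACED = 1
                        ) / 946,
                        af_vpc_fraction = 3 / 22,
                        grade_mix = c(`0` = 0.835, `1` = 0.128, `2a` = 0.027,
                                      `2b` = 0.008, `3` = 0.002),
                        low_voltage_fraction = 0.05,
                        repeat_two = 0.037, repeat_three = 0.003,
                        fs = 500, duration = 15) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects <= 0) {
    stop_invalid("`n_subjects` must be a positive integer")
  }
  for (nm in c("prevalence_gt65", "prevalence_le65", "male_fraction",
               "af_vpc_fraction", "low_voltage_fraction", "repeat_two",
               "repeat_three")) {
    assert_scalar_number(get(nm), nm, 0, 1)
  }
  if (any(rhythm_mix_non_af < 0) || abs(sum(rhythm_mix_non_af) - 1) > 1e-6) {
    stop_invalid("`rhythm_mix_non_af` must be non-negative and sum to 1")
  }
  if (any(grade_mix < 0) || abs(sum(grade_mix) - 1) > 1e-6) {
    stop_invalid("`grade_mix` must be non-negative and sum to 1")
  }
  if (!all(names(grade_mix) %in% c("0", "1", "2a", "2b", "3"))) {
    stop_invalid("`grade_mix` names must be among 0, 1, 2a, 2b, 3")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), seed = seed,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         age_max = age_max, prevalence_gt65 = prevalence_gt65,
         prevalence_le65 = prevalence_le65, male_fraction = male_fraction,
         rhythm_mix_non_af = rhythm_mix_non_af,
         af_vpc_fraction = af_vpc_fraction, grade_mix = grade_mix,
         low_voltage_fraction = low_voltage_fraction,
         repeat_two = repeat_two, repeat_three = repeat_three,
         fs = fs, duration = duration),
    class = "cohort_spec"
  )
}
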