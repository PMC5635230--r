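#' Construct a single-lead ECG record
#'
#' @param samples voltage samples in mV.
#' @param fs sampling rate, Hz.
#' @param duration recording length in seconds; `length(samples)` must equal
#'   `round(fs * duration)`.
#' @param subject_id,age subject metadata.
#' @param truth optional ground-truth list (rhythm class, R-peak times, beat
#'   types, corrupted intervals) carried by the generator.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, duration = length(samples) / fs,
                       subject_id = NA_character_, age = NA_real_,
                       truth = NULL) {
  assert_scalar_number(fs, "fs")
  if (fs <= 0) stop_invalid("`fs` must be > 0")
  if (duration <= 0) stop_invalid("`duration` must be > 0")
  if (length(samples) != round(fs * duration)) {
    stop_invalid("length(samples) must equal round(fs * duration)")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, duration = duration,
         subject_id = subject_id, age = age, truth = truth),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %.1f s at %g Hz (%d samples), subject %s%s\n",
    x$duration, x$fs, length(x$samples), x$subject_id,
    if (!is.null(x$truth)) paste0(", rhythm ", x$truth$rhythm_class) else ""
  ))
  invisible(x)
}

# Time axis of a record, in seconds starting at 0.
record_time <- function(rec) (seq_along(rec$samples) - 1) / rec$fs

draw_rr_base <- function(spec, n) {
  mean_rr <- 60 / spec$mean_hr
  draw <- function(k) {
    if (is_af_rhythm(spec$rhythm_class)) {
      # i.i.d. Gamma intervals: the irregularly-irregular AF pattern
      shape <- 1 / spec$rr_cv^2
      rgamma(k, shape = shape, scale = mean_rr / shape)
    } else if (spec$rr_cv == 0) {
      rep(mean_rr, k)
    } else {
      rnorm(k, mean_rr, spec$rr_cv * mean_rr)
    }
  }
  rr <- draw(n)
  # truncate to the physiological band [0.3, 2.0] s by redrawing
  for (i in 1:50) {
    bad <- rr < 0.3 | rr > 2.0
    if (!any(bad)) break
    rr[bad] <- draw(sum(bad))
  }
  pmin(pmax(rr, 0.3), 2.0)
}

#' Generate an RR-interval sequence for one recording
#'
#' Sinus-type rhythms draw low-variability intervals around `60 / mean_hr`;
#' AF draws i.i.d. Gamma intervals with coefficient of variation `rr_cv`
#' (default 0.24), truncated to \[0.3, 2.0\] s; ectopic classes insert
#' premature beats (coupling interval 0.55 of the mean RR) followed by a
#' non-compensatory (APC) or fully compensatory (VPC) pause. Intervals are
#' drawn until their sum covers `duration`.
#'
#' @param spec a [rhythm_spec()].
#' @param duration recording length in seconds.
#' @return numeric vector of RR intervals (s) with attributes
#'   `rhythm_class` and `ectopy` (data frame of inserted beat indices/types;
#'   beat `k` is the beat terminating interval `k - 1`).
#' @export
generate_rr_sequence <- function(spec, duration = 15) {
  if (!inherits(spec, "rhythm_spec")) stop_invalid("`spec` must be a rhythm_spec")
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop_invalid("`duration` must be > 0")
  }
  with_seed_maybe(spec$seed, {
    mean_rr <- 60 / spec$mean_hr
    n_max <- ceiling(duration / 0.3) + 2
    rr <- draw_rr_base(spec, n_max)
    n_kept <- which(cumsum(rr) >= duration)[1]
    if (is.na(n_kept)) n_kept <- length(rr)
    n_ect <- round(spec$ectopy_rate)
    ectopy <- data.frame(beat = integer(0), type = character(0))
    if (n_ect > 0 && spec$rhythm_class %in%
          c("SINUS_APC", "SINUS_VPC", "SINUS_APC_VPC", "AF_VPC")) {
      types <- switch(spec$rhythm_class,
        SINUS_APC = rep("APC", n_ect),
        SINUS_VPC = rep("VPC", n_ect),
        AF_VPC = rep("VPC", n_ect),
        SINUS_APC_VPC = rep(c("APC", "VPC"), length.out = n_ect)
      )
      # candidate interval pairs (k, k+1) inside the rendered stretch,
      # non-adjacent, away from the ends
      usable <- seq(2, max(2, n_kept - 2), by = 2)
      pick <- sort(sample(usable, min(n_ect, length(usable))))
      types <- types[seq_along(pick)]
      if (spec$rhythm_class != "AF_VPC") {
        # premature beat k terminates a short coupling interval; the pause
        # restores (VPC, compensatory) or undershoots (APC) the 2 * RR sum
        rr[pick] <- 0.55 * mean_rr
        rr[pick + 1] <- ifelse(types == "VPC", 1.45, 1.15) * mean_rr
      }
      ectopy <- data.frame(beat = pick + 1L, type = types,
                           stringsAsFactors = FALSE)
    }
    keep <- which(cumsum(rr) >= duration)[1]
    if (is.na(keep)) keep <- length(rr)
    rr <- rr[seq_len(keep)]
    ectopy <- ectopy[ectopy$beat <= keep + 1L, , drop = FALSE]
    structure(rr, rhythm_class = spec$rhythm_class, ectopy = ectopy,
              mean_hr = spec$mean_hr)
  })
}

# Add a Gaussian bump to `x` (sample grid `t`) centred at `center` seconds.
add_gauss <- function(x, t, fs, center, amp, sigma) {
  if (amp == 0) return(x)
  i0 <- max(1L, floor((center - 5 * sigma) * fs) + 1L)
  i1 <- min(length(x), ceiling((center + 5 * sigma) * fs) + 1L)
  if (i0 > i1) return(x)
  idx <- i0:i1
  x[idx] <- x[idx] + amp * exp(-((t[idx] - center)^2) / (2 * sigma^2))
  x
}

#' Render an ECG waveform from an RR sequence
#'
#' Each beat is a sum-of-Gaussians template (P unless suppressed, Q, R, S, T)
#' placed at the cumulative RR positions; the first R peak sits at
#' `first_r` seconds. AF classes render a continuous fibrillatory wave in
#' place of P waves. T-wave timing and width scale with the following RR
#' interval (Bazett-like), so rate changes do not push the T wave into the
#' next beat's P-wave window. The returned record's `truth` holds the exact
#' R-peak times and per-beat types.
#'
#' @param rr RR-interval vector, typically from [generate_rr_sequence()].
#' @param wf a [waveform_params()].
#' @param fs sampling rate in Hz (>= 100).
#' @param duration recording length, seconds.
#' @param rhythm_class rhythm label; defaults to the `rhythm_class` attribute
#'   of `rr`.
#' @param first_r time of the first R peak, seconds.
#' @param subject_id,age metadata copied into the record.
#' @return an [ecg_record()].
#' @export
synthesize_ecg <- function(rr, wf, fs = 500, duration = 15,
                           rhythm_class = NULL, first_r = 0.35,
                           subject_id = NA_character_, age = NA_real_) {
  if (length(rr) == 0) stop_invalid("`rr` must be non-empty")
  if (!inherits(wf, "waveform_params")) stop_invalid("`wf` must be waveform_params")
  if (fs < 100) stop_invalid("`fs` must be >= 100 Hz")
  if (6 * wf$qrs_width * fs < 4) {
    stop_invalid("`fs` too low to resolve the QRS width")
  }
  rhythm_class <- rhythm_class %||% attr(rr, "rhythm_class") %||% "SINUS"
  wf <- waveform_for_class(wf, rhythm_class)
  ectopy <- attr(rr, "ectopy") %||% data.frame(beat = integer(0), type = character(0))

  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)

  beats <- first_r + c(0, cumsum(rr))
  keep <- beats <= duration - 0.12
  beats <- beats[keep]
  beat_type <- rep(if (rhythm_class == "PACED") "PACED" else "N", length(beats))
  if (nrow(ectopy) > 0) {
    ok <- ectopy$beat <= length(beats)
    beat_type[ectopy$beat[ok]] <- ectopy$type[ok]
  }
  rr_next <- c(diff(beats), Inf)

  A <- wf$qrs_amplitude
  for (j in seq_along(beats)) {
    r <- beats[j]
    type <- beat_type[j]
    if (type == "VPC") {
      # wide, large-amplitude ventricular beat: no P, inverted T
      x <- add_gauss(x, t, fs, r, 0.85 * 1.3 * A, 2.5 * wf$qrs_width)
      x <- add_gauss(x, t, fs, r + 0.07, -0.25 * 1.3 * A, 0.02)
      tc <- min(0.29 * sqrt(min(rr_next[j], 1.2)), rr_next[j] - 0.28)
      if (is.finite(tc) && tc > 0.1) {
        x <- add_gauss(x, t, fs, r + tc + 0.05, -wf$t_amplitude, wf$t_width)
      }
    } else {
      if (type == "N" && wf$p_amplitude > 0) {
        x <- add_gauss(x, t, fs, r - 0.16, wf$p_amplitude, wf$p_width)
      }
      if (type == "PACED") {
        # narrow pacing spike preceding the QRS
        x <- add_gauss(x, t, fs, r - 0.045, 0.5, 0.002)
      }
      x <- add_gauss(x, t, fs, r - 0.030, -0.08 * A, 0.009)
      x <- add_gauss(x, t, fs, r, 0.85 * A, wf$qrs_width)
      x <- add_gauss(x, t, fs, r + 0.035, -0.18 * A, 0.008)
      tc <- 0.29 * sqrt(min(rr_next[j], 1.2))
      if (is.finite(rr_next[j]) || beats[j] + tc < duration - 0.05) {
        x <- add_gauss(x, t, fs, r + tc, wf$t_amplitude,
                       0.045 * sqrt(min(rr_next[j], 1.2)))
      }
    }
  }

  if (is_af_rhythm(rhythm_class) && wf$f_wave_amplitude > 0) {
    # continuous fibrillatory baseline: amplitude-modulated sinusoid
    x <- x + wf$f_wave_amplitude * (0.8 + 0.2 * sin(2 * pi * 0.9 * t)) *
      sin(2 * pi * wf$f_wave_freq * t + 0.7)
  }

  ecg_record(
    x, fs = fs, duration = duration, subject_id = subject_id, age = age,
    truth = list(rhythm_class = rhythm_class, r_peaks = beats,
                 beat_types = beat_type, rr = rr,
                 n_ectopic = sum(beat_type %in% c("APC", "VPC")),
                 corrupted_intervals = NULL, qrs_amplitude = A)
  )
}

#' Add baseline wander, broadband noise and burst corruption to a record
#'
#' Zero-noise specifications return the input unchanged. Burst corruption is
#' injected as one contiguous interval covering `corrupted_fraction` of the
#' recording (its boundaries are stored in `truth$corrupted_intervals`).
#'
#' @param rec an [ecg_record()].
#' @param noise a [noise_spec()].
#' @return the corrupted [ecg_record()].
#' @export
add_artifacts <- function(rec, noise) {
  if (!inherits(rec, "ecg_record")) stop_invalid("`rec` must be an ecg_record")
  if (!inherits(noise, "noise_spec")) stop_invalid("`noise` must be a noise_spec")
  if (is_zero_noise(noise)) return(rec)
  with_seed_maybe(noise$seed, {
    t <- record_time(rec)
    x <- rec$samples
    if (noise$baseline_wander_amplitude > 0) {
      phase <- runif(1, 0, 2 * pi)
      x <- x + noise$baseline_wander_amplitude *
        sin(2 * pi * noise$baseline_wander_freq * t + phase)
    }
    if (noise$broadband_noise_sd > 0) {
      x <- x + rnorm(length(x), 0, noise$broadband_noise_sd)
    }
    corrupted <- NULL
    if (noise$corrupted_fraction > 0) {
      len <- noise$corrupted_fraction * rec$duration
      start <- if (len >= rec$duration) 0 else runif(1, 0, rec$duration - len)
      idx <- which(t >= start & t < start + len)
      x[idx] <- x[idx] + rnorm(length(idx), 0, noise$burst_noise_sd)
      corrupted <- matrix(c(start, start + len), nrow = 1,
                          dimnames = list(NULL, c("start", "end")))
    }
    rec$samples <- x
    rec$truth$corrupted_intervals <- corrupted
    rec$noise <- noise
    rec
  })
}
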