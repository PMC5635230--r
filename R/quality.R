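#' Measured fraction of artifact-bearing time
#'
#' The recording is split into 1 s windows; a window is flagged when its
#' robust high-frequency noise estimate (median absolute deviation of the
#' first difference, scaled to an SD) exceeds `noise_threshold`, or when the
#' trace leaves the `clip_limit` voltage range. The MAD makes the estimate
#' insensitive to the QRS complexes themselves, which occupy only a small
#' share of each window's samples.
#'
#' @param rec an [ecg_record()] (typically baseline-removed).
#' @param noise_threshold per-window noise SD above which the window counts
#'   as artifact, mV.
#' @param clip_limit absolute voltage treated as saturation, mV.
#' @return fraction of flagged windows in \[0, 1\], with attribute
#'   `flagged_intervals` (matrix of window start/end times).
#' @export
artifact_fraction <- function(rec, noise_threshold = 0.08, clip_limit = 4) {
  if (!inherits(rec, "ecg_record")) stop_invalid("`rec` must be an ecg_record")
  fs <- rec$fs
  n_win <- max(1L, floor(rec$duration))
  flags <- logical(n_win)
  for (k in seq_len(n_win)) {
    idx <- (round((k - 1) * fs) + 1L):min(length(rec$samples), round(k * fs))
    w <- rec$samples[idx]
    noise_sd <- mad(diff(w)) / sqrt(2)
    flags[k] <- noise_sd > noise_threshold || any(abs(w) > clip_limit)
  }
  iv <- cbind(start = which(flags) - 1, end = which(flags))
  structure(mean(flags), flagged_intervals = iv)
}

#' Residual baseline-wander level after filtering
#'
#' Root-mean-square amplitude in the 0.05--0.55 Hz band (via the discrete
#' Fourier transform), classified as `"none"`, `"mild"` or `"significant"`.
#' Evaluated on the baseline-removed record: wander that survives the
#' highpass is what still interferes with P-wave reading.
#'
#' @param rec a baseline-removed [ecg_record()].
#' @param mild_rms,significant_rms band RMS thresholds in mV.
#' @return factor level among none/mild/significant with attribute `rms`.
#' @export
wander_level <- function(rec, mild_rms = 0.04, significant_rms = 0.25) {
  x <- rec$samples
  n <- length(x)
  freqs <- (seq_len(n) - 1) * rec$fs / n
  X <- fft(x)
  band <- which(freqs >= 0.05 & freqs <= 0.55)
  # one-sided band power -> RMS of the band-limited component
  rms <- sqrt(2 * sum(Mod(X[band])^2) / n^2)
  lev <- if (rms >= significant_rms) "significant" else
    if (rms >= mild_rms) "mild" else "none"
  structure(lev, rms = rms)
}

#' Grade recording quality on the 0/1/2a/2b/3 artifact scale
#'
#' Grade 0: negligible artifact (< 5% flagged time) and no residual wander.
#' Grade 1: artifact fraction < 33%. Grade 2a: artifact fraction 33--66%
#' (66% inclusive) or mild residual wander. Grade 2b: artifact fraction
#' > 66% or significant wander (which interferes with P-wave recognition).
#' Grade 3: no recognizable QRS complexes -- the sink state for flat,
#' saturated or overwhelmingly noisy records, excluded from screening
#' performance analysis. P-wave recognizability is recorded (scored on
#' non-flagged windows) but does not by itself worsen the grade: absent P
#' waves are a rhythm feature (AF, junctional) as much as a quality feature.
#'
#' @param rec a baseline-removed [ecg_record()].
#' @param features an [extract_features()] result for `rec` (computed if
#'   missing).
#' @return an object of class `quality_grade` with fields `grade` (one of
#'   `"0","1","2a","2b","3"`), `artifact_fraction`, `p_recognizable`,
#'   `qrs_recognizable`, `wander_flag`.
#' @export
grade_quality <- function(rec, features = extract_features(rec)) {
  af <- artifact_fraction(rec)
  wl <- wander_level(rec)
  n_beats <- features$n_beats

  # a recognizable QRS train: a plausible number of beats for 15 s and
  # peak amplitudes standing clear of the background noise
  noise_global <- mad(diff(rec$samples)) / sqrt(2)
  peak_amp <- attr(features$r_peaks, "amplitudes")
  med_amp <- if (length(peak_amp)) median(peak_amp) else 0
  max_beats <- ceiling(rec$duration * 220 / 60)
  qrs_rec <- n_beats >= 4 && n_beats <= max_beats &&
    med_amp >= max(0.08, 2.5 * noise_global)

  p_rec <- FALSE
  if (qrs_rec) {
    ps <- tryCatch(
      p_wave_score(rec, features$r_peaks,
                   exclude_intervals = attr(af, "flagged_intervals")),
      afscreen_insufficient_beats = function(e) features$p_score
    )
    p_rec <- !is.na(ps) && ps >= 0.5
  }

  grade <- if (!qrs_rec) "3"
  else if (af > 0.66 || wl == "significant") "2b"
  else if (af >= 0.33 || wl == "mild") "2a"
  else if (af < 0.05) "0"
  else "1"

  structure(
    list(grade = grade, artifact_fraction = as.numeric(af),
         p_recognizable = p_rec, qrs_recognizable = qrs_rec,
         wander_flag = as.character(wl)),
    class = "quality_grade"
  )
}

#' @export
print.quality_grade <- function(x, ...) {
  cat(sprintf("<quality_grade> grade %s (artifact %.0f%%, wander %s, QRS %s, P %s)\n",
              x$grade, 100 * x$artifact_fraction, x$wander_flag,
              if (x$qrs_recognizable) "recognizable" else "not recognizable",
              if (x$p_recognizable) "recognizable" else "not recognizable"))
  invisible(x)
}
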