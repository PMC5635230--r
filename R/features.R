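#' Detect QRS complexes (R peaks)
#'
#' Energy-based detector in the Pan-Tompkins style: 5--25 Hz zero-phase FIR
#' bandpass, differentiation, squaring, 150 ms centred moving-window
#' integration, then peak selection with running signal/noise levels and a
#' 200 ms refractory period. Each accepted energy peak is refined to the
#' maximum of the (baseline-removed) waveform within +/- 80 ms, which lands
#' on the R apex rather than on pacing spikes or integration-window edges.
#'
#' @param rec a baseline-removed [ecg_record()].
#' @return strictly increasing R-peak times in seconds (empty for a signal
#'   with no detectable energy), with attribute `amplitudes` (waveform value
#'   at each peak).
#' @export
detect_qrs <- function(rec) {
  if (!inherits(rec, "ecg_record")) stop_invalid("`rec` must be an ecg_record")
  fs <- rec$fs
  x <- rec$samples
  n <- length(x)

  bp <- design_fir(filter_spec("bandpass", cutoff_low = 5, cutoff_high = 25,
                               numtaps = 2 * floor(0.25 * fs / 2) + 1), fs)
  y <- apply_fir_zero_phase(x, bp)
  d <- c(0, diff(y)) * fs
  e <- d^2
  w <- max(3L, round(0.15 * fs))
  if (w %% 2 == 0) w <- w + 1L
  z <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  z[is.na(z)] <- 0

  if (max(z) < 1e-9) return(structure(numeric(0), amplitudes = numeric(0)))

  # strict local maxima of the integrated energy
  cand <- which(diff(sign(diff(z))) == -2) + 1L
  if (length(cand) == 0) return(structure(numeric(0), amplitudes = numeric(0)))
  refractory <- round(0.2 * fs)

  spk <- max(z[seq_len(min(n, round(2.5 * fs)))])
  npk <- median(z)
  accepted <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npk + 0.25 * (spk - npk)
    if (z[i] >= thr) {
      if (i - last >= refractory) {
        accepted <- c(accepted, i)
        last <- i
        spk <- 0.125 * z[i] + 0.875 * spk
      } else if (z[i] > z[last]) {
        accepted[length(accepted)] <- i
        last <- i
        spk <- 0.125 * z[i] + 0.875 * spk
      }
    } else {
      npk <- 0.125 * z[i] + 0.875 * npk
    }
  }
  if (length(accepted) == 0) return(structure(numeric(0), amplitudes = numeric(0)))

  # refine to the waveform apex
  half <- round(0.08 * fs)
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))

  # enforce the refractory period after refinement, keeping the larger peak
  if (length(peaks) > 1) {
    keep <- rep(TRUE, length(peaks))
    j <- 1
    for (i in 2:length(peaks)) {
      if (peaks[i] - peaks[j] < refractory) {
        if (x[peaks[i]] > x[peaks[j]]) { keep[j] <- FALSE; j <- i }
        else keep[i] <- FALSE
      } else j <- i
    }
    peaks <- peaks[keep]
  }
  structure((peaks - 1) / fs, amplitudes = x[peaks])
}

#' RR-interval irregularity statistics
#'
#' @param rr RR intervals in seconds (at least 3).
#' @param delta_threshold threshold on successive differences, seconds
#'   (default 0.05, the pNN50 convention).
#' @return list with `rr_cv` (sample SD over mean, n-1 denominator),
#'   `rr_rmssd_norm` (root-mean-square of successive differences over the
#'   mean) and `pct_delta_rr_gt` (fraction of successive differences
#'   exceeding `delta_threshold`).
#' @export
rr_statistics <- function(rr, delta_threshold = 0.05) {
  if (length(rr) < 3) {
    stop_insufficient_beats("at least 3 RR intervals are required")
  }
  if (any(rr <= 0)) stop_invalid("RR intervals must be positive")
  m <- mean(rr)
  dr <- diff(rr)
  list(
    rr_cv = sd(rr) / m,
    rr_rmssd_norm = sqrt(mean(dr^2)) / m,
    pct_delta_rr_gt = mean(abs(dr) > delta_threshold)
  )
}

# RR statistics restricted to intervals whose bounding peaks both lie
# outside artifact-flagged windows; successive differences are taken only
# within contiguous runs of clean intervals. Falls back to the full
# sequence when fewer than 3 clean intervals (or 2 clean differences)
# remain.
rr_statistics_clean <- function(rr, r_peaks, flagged) {
  if (is.null(flagged) || nrow(flagged) == 0) return(rr_statistics(rr))
  in_flagged <- vapply(r_peaks, function(t) {
    any(t >= flagged[, "start"] & t < flagged[, "end"])
  }, logical(1))
  clean <- !in_flagged[-length(in_flagged)] & !in_flagged[-1]
  # spurious detections split real intervals into implausible fragments;
  # the gate is wide enough to keep AF variability and ectopic coupling
  med <- median(if (sum(clean) >= 3) rr[clean] else rr)
  clean <- clean & rr >= 0.4 * med & rr <= 1.8 * med
  runs <- rle(clean)
  ends <- cumsum(runs$lengths)
  d <- unlist(lapply(which(runs$values & runs$lengths >= 2), function(k) {
    idx <- (ends[k] - runs$lengths[k] + 1):ends[k]
    diff(rr[idx])
  }))
  if (sum(clean) < 3 || length(d) < 2) return(rr_statistics(rr))
  m <- mean(rr[clean])
  list(
    rr_cv = sd(rr[clean]) / m,
    rr_rmssd_norm = sqrt(mean(d^2)) / m,
    pct_delta_rr_gt = mean(abs(d) > 0.05)
  )
}

#' Score P-wave presence
#'
#' For each beat the window \[R - 250 ms, R - 80 ms\] is examined, with
#' voltages taken relative to the window's median (the local baseline). A
#' beat counts as P-bearing when its largest positive deflection (i) exceeds
#' `max(0.05 mV, 2 x local noise SD)`, (ii) dominates the window (at least
#' 1.8 times the mean absolute deviation from the baseline), (iii) rises
#' from a quiet isoelectric segment (at least 40% of the window below a
#' quarter of the deflection) -- continuous fibrillatory waves fail these
#' two -- and (iv) is timed consistently with the other beats (within 30 ms
#' of the median offset). The score is the
#' fraction of evaluable beats that qualify; it is deterministic given the
#' record.
#'
#' @param rec a baseline-removed [ecg_record()].
#' @param r_peaks R-peak times in seconds (>= 3).
#' @param exclude_intervals optional matrix with columns `start`, `end`
#'   (seconds); beats whose P window overlaps an excluded interval are not
#'   evaluated (used to score quality on artifact-free windows only).
#' @return `p_score` in \[0, 1\].
#' @export
p_wave_score <- function(rec, r_peaks, exclude_intervals = NULL) {
  if (length(r_peaks) < 3) {
    stop_insufficient_beats("at least 3 beats are required to score P waves")
  }
  fs <- rec$fs
  x <- rec$samples
  win <- c(-0.25, -0.08)
  amp <- off <- dom <- thr <- quiet <- rep(NA_real_, length(r_peaks))
  for (j in seq_along(r_peaks)) {
    a <- r_peaks[j] + win[1]
    b <- r_peaks[j] + win[2]
    if (a < 0) next
    if (!is.null(exclude_intervals) && nrow(exclude_intervals) > 0 &&
        any(a < exclude_intervals[, "end"] & b > exclude_intervals[, "start"])) {
      next
    }
    idx <- (floor(a * fs) + 1L):(min(length(x), floor(b * fs) + 1L))
    # deflections are measured against the local window baseline: the
    # highpass leaves a small negative offset under each beat complex
    w <- x[idx] - median(x[idx])
    k <- which.max(w)
    amp[j] <- w[k]
    off[j] <- (idx[k] - 1) / fs - r_peaks[j]
    dom[j] <- w[k] / max(mean(abs(w)), 1e-9)
    noise_sd <- mad(diff(w)) / sqrt(2)
    thr[j] <- max(0.05, 2 * noise_sd)
    # a distinct P wave sits on a flat isoelectric segment; continuous
    # fibrillatory waves leave no quiet baseline around their humps
    quiet[j] <- mean(abs(w) < max(0.25 * w[k], 2.5 * noise_sd, 0.05))
  }
  ok <- !is.na(amp)
  if (sum(ok) < 3) {
    stop_insufficient_beats("fewer than 3 evaluable P-wave windows")
  }
  med_off <- median(off[ok])
  present <- ok & amp >= thr & dom >= 1.8 & quiet >= 0.4 &
    abs(off - med_off) <= 0.03
  sum(present, na.rm = TRUE) / sum(ok)
}

#' Median QRS amplitude
#'
#' Median peak-to-trough voltage within +/- 60 ms of each R peak.
#'
#' @param rec a baseline-removed [ecg_record()].
#' @param r_peaks R-peak times, seconds (at least one).
#' @return amplitude in mV.
#' @export
qrs_amplitude <- function(rec, r_peaks) {
  if (length(r_peaks) < 1) {
    stop_insufficient_beats("at least 1 beat is required to measure QRS amplitude")
  }
  fs <- rec$fs
  x <- rec$samples
  half <- round(0.06 * fs)
  amps <- vapply(r_peaks, function(r) {
    i <- round(r * fs) + 1L
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    max(x[lo:hi]) - min(x[lo:hi])
  }, numeric(1))
  median(amps)
}

#' Extract the feature vector of one record
#'
#' Runs QRS detection (unless peaks are supplied), RR statistics, the P-wave
#' score and the QRS amplitude. Records with fewer than 3 detected beats
#' yield `insufficient = TRUE` with `NA` statistics, signalling that the
#' record cannot be auto-classified.
#'
#' @param rec a baseline-removed [ecg_record()].
#' @param r_peaks optional precomputed R-peak times.
#' @return an object of class `ecg_features`: `r_peaks`, `rr`, `n_beats`,
#'   `rr_cv`, `rr_rmssd_norm`, `pct_delta_rr_gt`, `p_score`, `qrs_amp`,
#'   `insufficient`.
#' @export
extract_features <- function(rec, r_peaks = NULL) {
  r_peaks <- r_peaks %||% detect_qrs(rec)
  n_beats <- length(r_peaks)
  out <- list(r_peaks = r_peaks, rr = diff(r_peaks), n_beats = n_beats,
              rr_cv = NA_real_, rr_rmssd_norm = NA_real_,
              pct_delta_rr_gt = NA_real_, p_score = NA_real_,
              qrs_amp = NA_real_, insufficient = TRUE)
  flagged <- attr(artifact_fraction(rec), "flagged_intervals")
  if (n_beats >= 4) {
    st <- rr_statistics_clean(out$rr, r_peaks, flagged)
    out[names(st)] <- st
    # score P waves on artifact-free windows; fall back to all windows when
    # too few clean ones remain (heavily corrupted records)
    out$p_score <- tryCatch(
      p_wave_score(rec, r_peaks, exclude_intervals = flagged),
      afscreen_insufficient_beats = function(e) {
        tryCatch(p_wave_score(rec, r_peaks),
                 afscreen_insufficient_beats = function(e) NA_real_)
      }
    )
    out$qrs_amp <- qrs_amplitude(rec, r_peaks)
    out$insufficient <- is.na(out$p_score)
  }
  structure(out, class = "ecg_features")
}

#' Feature rows for a list of records
#'
#' @param features list of `ecg_features`.
#' @param record_ids record identifiers.
#' @return data frame with one row per record
#'   (`record_id, n_beats, rr_cv, rr_rmssd_norm, pnn50, p_score, qrs_amp`).
#' @export
features_to_df <- function(features, record_ids = seq_along(features)) {
  data.frame(
    record_id = record_ids,
    n_beats = vapply(features, `[[`, numeric(1), "n_beats"),
    rr_cv = vapply(features, `[[`, numeric(1), "rr_cv"),
    rr_rmssd_norm = vapply(features, `[[`, numeric(1), "rr_rmssd_norm"),
    pnn50 = vapply(features, `[[`, numeric(1), "pct_delta_rr_gt"),
    p_score = vapply(features, `[[`, numeric(1), "p_score"),
    qrs_amp = vapply(features, `[[`, numeric(1), "qrs_amp"),
    stringsAsFactors = FALSE
  )
}
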