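#' FIR filter specification
#'
#' Baseline removal uses a linear-phase finite impulse response (FIR)
#' highpass. The default cutoff of 0.67 Hz is the classic diagnostic-ECG
#' baseline bound; the default length of 4 s of taps (rounded to odd, so the
#' group delay is an integer number of samples) puts the -20 dB point safely
#' below half the cutoff.
#'
#' @param kind `"highpass"` or `"bandpass"`.
#' @param cutoff_low low cutoff, Hz.
#' @param cutoff_high high cutoff, Hz (bandpass only).
#' @param numtaps odd number of taps; default `4 * fs` rounded to odd,
#'   resolved at design time.
#' @param window taper name: `"hamming"`, `"hanning"` or `"blackman"`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "bandpass"), cutoff_low = 0.67,
                        cutoff_high = NULL, numtaps = NULL,
                        window = "hamming") {
  kind <- match.arg(kind)
  assert_scalar_number(cutoff_low, "cutoff_low")
  if (cutoff_low <= 0) stop_invalid("`cutoff_low` must be > 0")
  if (kind == "bandpass") {
    if (is.null(cutoff_high)) stop_invalid("bandpass needs `cutoff_high`")
    if (cutoff_high <= cutoff_low) stop_invalid("`cutoff_high` must exceed `cutoff_low`")
  }
  if (!is.null(numtaps)) {
    if (numtaps < 3 || numtaps %% 2 != 1) {
      stop_invalid("`numtaps` must be odd and >= 3 (exact linear phase)")
    }
  }
  window <- match.arg(window, c("hamming", "hanning", "blackman"))
  structure(
    list(kind = kind, cutoff_low = cutoff_low, cutoff_high = cutoff_high,
         numtaps = numtaps, window = window),
    class = "filter_spec"
  )
}

resolve_numtaps <- function(spec, fs) {
  nt <- spec$numtaps %||% (2 * floor(4 * fs / 2) + 1)
  if (nt %% 2 == 0) nt <- nt + 1
  nt
}

#' Design a linear-phase FIR filter
#'
#' Windowed-sinc design via [signal::fir1()]. Coefficients are symmetric
#' (type I), so a single centred convolution applies the filter with exactly
#' zero phase.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @return numeric coefficient vector with attributes `fs` and `spec`.
#' @export
design_fir <- function(spec, fs) {
  if (!inherits(spec, "filter_spec")) stop_invalid("`spec` must be a filter_spec")
  nyq <- fs / 2
  hi <- spec$cutoff_high %||% Inf
  if (spec$cutoff_low >= nyq || (is.finite(hi) && hi >= nyq)) {
    stop_invalid("filter cutoffs must be below the Nyquist frequency")
  }
  nt <- resolve_numtaps(spec, fs)
  win <- switch(spec$window,
    hamming = signal::hamming(nt),
    hanning = signal::hanning(nt),
    blackman = signal::blackman(nt)
  )
  b <- if (spec$kind == "highpass") {
    signal::fir1(nt - 1, spec$cutoff_low / nyq, type = "high", window = win)
  } else {
    signal::fir1(nt - 1, c(spec$cutoff_low, spec$cutoff_high) / nyq,
                 type = "pass", window = win)
  }
  b <- as.numeric(b)
  # force H(0) = 0 exactly so a DC offset is fully rejected; the per-tap
  # adjustment is ~1e-6 and leaves the rest of the response unchanged
  if (spec$kind == "highpass") b <- b - sum(b) / length(b)
  structure(b, fs = fs, spec = spec)
}

#' Magnitude response of an FIR filter
#'
#' @param b coefficient vector from [design_fir()].
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate, Hz (defaults to the `fs` attribute of `b`).
#' @return `|H(f)|`, same length as `f`.
#' @export
fir_response <- function(b, f, fs = attr(b, "fs")) {
  k <- seq_along(b) - 1
  vapply(f, function(fi) {
    Mod(sum(b * exp(-2i * pi * fi * k / fs)))
  }, numeric(1))
}

# Zero-phase FIR application: reflect-pad by half the filter length, convolve
# with the symmetric kernel centred on each sample, keep the valid core.
apply_fir_zero_phase <- function(x, b) {
  m <- (length(b) - 1) / 2
  n <- length(x)
  left <- 2 * x[1] - x[(m + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - m)]
  xp <- c(left, x, right)
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  as.numeric(y[(m + 1):(m + n)])
}

#' Remove baseline noise from a record
#'
#' Applies the highpass FIR with zero phase (symmetric kernel, centred
#' convolution with reflected padding), so R-peak times are not shifted and
#' the sample count is preserved.
#'
#' @param rec an [ecg_record()].
#' @param spec a [filter_spec()]; default 0.67 Hz highpass.
#' @return the filtered [ecg_record()].
#' @export
remove_baseline <- function(rec, spec = filter_spec()) {
  if (!inherits(rec, "ecg_record")) stop_invalid("`rec` must be an ecg_record")
  nt <- resolve_numtaps(spec, rec$fs)
  if (length(rec$samples) <= nt) {
    stop(errorCondition(
      sprintf("record (%d samples) shorter than the filter (%d taps)",
              length(rec$samples), nt),
      class = c("afscreen_invalid_input", "error", "condition")
    ))
  }
  b <- design_fir(spec, rec$fs)
  rec$samples <- apply_fir_zero_phase(rec$samples, b)
  rec$filtered <- TRUE
  rec
}
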