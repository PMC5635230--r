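# Shared fixture builders: all synthetic, all seeded.

make_record <- function(rhythm_class = "SINUS", mean_hr = 62, seed = 1,
                        wf = waveform_params(), noise = NULL, fs = 500,
                        duration = 15, rr_cv = NULL) {
  spec <- rhythm_spec(rhythm_class, mean_hr = mean_hr, rr_cv = rr_cv,
                      seed = seed)
  rr <- generate_rr_sequence(spec, duration)
  rec <- synthesize_ecg(rr, wf, fs = fs, duration = duration)
  if (!is.null(noise)) rec <- add_artifacts(rec, noise)
  rec
}

make_filtered <- function(...) remove_baseline(make_record(...))

# precision / recall of detected peaks against truth at a time tolerance
match_peaks <- function(detected, truth, tol = 0.02) {
  tp <- sum(vapply(detected, function(p) any(abs(truth - p) <= tol), logical(1)))
  list(
    precision = if (length(detected)) tp / length(detected) else NA_real_,
    recall = sum(vapply(truth, function(p) any(abs(detected - p) <= tol),
                        logical(1))) / length(truth)
  )
}
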