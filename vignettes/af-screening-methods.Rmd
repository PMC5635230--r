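---
title: "Methods: simulated single-lead AF screening and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated single-lead AF screening and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afscreen)
```

## What the package models

Community atrial-fibrillation (AF) screening with a handheld single-lead
recorder produces short (15 s) lead-II-like ECG strips that an automated
algorithm must sort into *AF* / *not AF*, with a recording-quality grade
deciding whether the strip is interpretable at all. The electrocardiographic
definition of AF is the conjunction of two features: **irregularly irregular
RR intervals** and **no discernible, distinct P waves**. `afscreen`
implements that whole chain — signal synthesis, baseline-noise removal,
feature extraction, quality grading, the rule-based decision, and the
age-stratified diagnostic-test evaluation — so every stage can be tested
against exact ground truth.

Because no raw recordings from such screening campaigns are public, the
package carries its own generator; the published summary counts of one
campaign (967 ECGs from 922 residents, 22 AF) serve as the fixed input for
the evaluation-stage reconstruction.

## The synthetic ECG generator

### Rhythm model

RR intervals are drawn per rhythm class (`generate_rr_sequence()`):

* **Sinus, junctional, paced** — normal around $60/\mathrm{HR}$ s with a
  class-typical coefficient of variation (CV): 0.04 sinus, 0.03
  junctional, 0.01 paced. All draws are truncated to the physiological
  band [0.3, 2.0] s.
* **AF** — i.i.d. Gamma intervals with CV 0.24 (shape $1/0.24^2$),
  truncated identically. The i.i.d. Gamma model is the simplest seedable
  realization of the irregularly-irregular pattern; it ignores the weak
  serial correlation of real AF, which none of the implemented statistics
  (CV, RMSSD, pNN50) are sensitive to.
* **Ectopy** — an atrial premature complex (APC) replaces an interval pair
  with a 0.55·RR coupling interval and a non-compensatory 1.15·RR pause; a
  ventricular premature complex (VPC) couples identically but with a fully
  compensatory 1.45·RR pause. Default three ectopic beats per affected
  recording. These are the beats that make RR-only AF detectors fire
  falsely, which is exactly the failure mode the evaluation exercises.

### Morphology

Each beat is a sum of Gaussians (P, Q, R, S, T), the standard synthetic-ECG
device. Amplitudes are in millivolts; `qrs_amplitude` parameterizes the
realized *peak-to-trough* QRS voltage (R 0.85·A, S −0.18·A), so the
low-voltage false-positive mode of real screening data is expressible
directly as `qrs_amplitude < 0.5`. T-wave timing and width scale with
$\sqrt{RR}$ (Bazett-like), keeping the T wave clear of the next beat's
P-wave window at short cycle lengths. AF and AF+VPC render a continuous
amplitude-modulated fibrillatory wave (default 0.1 mV at 6 Hz, i.e. an
atrial rate of 360/min) instead of P waves; junctional and paced rhythms
render no atrial activity at all, and paced beats carry a 0.5 mV, 2 ms
pacing spike 45 ms before the QRS.

### Noise and cohorts

`add_artifacts()` adds (i) sinusoidal baseline wander below 0.5 Hz,
(ii) stationary Gaussian broadband noise, and (iii) a contiguous burst of
high-amplitude noise covering exactly `corrupted_fraction` of the
recording, with the burst boundaries stored as truth. A zero spec is the
identity.

`generate_cohort()` draws a screening population whose defaults are the
study conditions: age $\mathcal N(58.1, 15^2)$ truncated to [20, 95],
36.6% male, subject-level AF prevalence 4.1% above age 65 and 0.8% at or
below, the observed conditional rhythm mix among non-AF subjects, repeat
recordings for ~4% of subjects, artifact grades injected at
83.5/12.8/2.7/0.8/0.2%, and 5% of recordings in the low-voltage mode.
Heart rates are $\mathcal N(72, 8^2)$ bpm for non-AF and
$\mathcal N(88, 12^2)$ for AF subjects. Grade classes map to noise
recipes; grade 3 is an electrode-failure proxy (near-zero cardiac signal
under continuous burst noise). Everything derives from one master seed;
per-record sub-seeds are recorded in the manifest.

What the generator does **not** emulate: muscle-artifact spectra shaped
like real EMG, electrode pop transients, atrial flutter (regular f waves),
respiratory modulation, or morphology variability between beats beyond the
ectopy classes. Tests passing on these fixtures therefore demonstrate the
pipeline's logic and calibration on idealized but adversarially structured
data (ectopy, low voltage, coarse f waves, graded corruption), not
clinical-grade performance.

## Baseline removal

A linear-phase FIR highpass (`filter_spec()`, `design_fir()`): cutoff
0.67 Hz — the classic diagnostic-ECG baseline bound — Hamming window, and
4 s of taps rounded to odd (2001 at 500 Hz). Three seconds of taps would
leave the −20 dB point above half the cutoff (|H(0.335 Hz)| ≈ 0.13); four
seconds gives |H(0.3)| ≈ 0.04 and |H(0.335)| ≈ 0.07 while passing 1 Hz at
0.99. The symmetric kernel is applied as a single *centred* convolution
with reflective padding (`remove_baseline()`), which is exactly zero-phase:
R-peak times shift by less than one sample. The coefficient sum is zeroed
after windowing so a DC offset is rejected exactly. The deployed system's
filter parameters and causality are unknown; these are conventional,
testable choices.

## Feature extraction

### QRS detection

`detect_qrs()` is the field-standard energy detector: 5–25 Hz zero-phase
FIR bandpass, differentiation, squaring, 150 ms centred moving-window
integration, running signal/noise levels with threshold
$\mathrm{NPK} + 0.25(\mathrm{SPK} - \mathrm{NPK})$, a 200 ms refractory
period, and refinement of each energy peak to the waveform maximum within
±80 ms. The refinement step is what keeps pacing spikes, wide VPCs and
0.4 mV low-voltage beats on the R apex. On noise-free fixtures of every
rhythm class, precision and recall are 1.0 at ±20 ms (this is a test).

### RR statistics

`rr_statistics()` computes CV (sample SD over mean, $n-1$ denominator),
RMSSD normalized by the mean RR, and pNN50 (fraction of successive
differences above 50 ms, the standard HRV convention). Within
`extract_features()` these are computed on *clean* intervals: intervals
whose bounding peaks fall in artifact-flagged 1 s windows are dropped, as
are intervals outside [0.4, 1.8]× the median RR (spurious detections split
real intervals into implausible fragments; the band is wide enough to keep
genuine AF variability and ectopic coupling intervals). If fewer than
three clean intervals survive, the full sequence is used.

### P-wave score

For each beat the window [R−250 ms, R−80 ms] is examined relative to its
median (the local baseline — the highpass leaves a small negative offset
under each beat complex). A beat is P-bearing when its largest positive
deflection

1. exceeds max(0.05 mV, 2 × local noise SD),
2. dominates the window: ≥ 1.8 × the mean absolute deviation,
3. rises from a quiet isoelectric segment: ≥ 40% of the window lies below
   max(deflection/4, 2.5 × noise SD, 0.05 mV), and
4. is timed consistently: within 30 ms of the median offset across beats.

`p_score` is the fraction of evaluable beats qualifying. Criterion (3) is
the operational meaning of "distinct": a true P wave is a discrete bump on
a flat segment, whereas a fibrillatory wave fills the window with
oscillation. It matters because a 6 Hz f wave has a period (167 ms)
close to the window length, so exactly one of its humps can otherwise
masquerade as a P wave. Windows overlapping artifact-flagged seconds are
skipped, with a whole-record fallback when fewer than three clean windows
remain. On fixtures, sinus scores ≥ 0.9, AF ≤ 0.38, junctional 0, and the
score is monotone in the generated P amplitude.

## Quality grading

"Artifact percentage" is not defined in the source report; here it is the
**time fraction of flagged 1 s windows** (`artifact_fraction()`), a window
being flagged when its robust noise estimate (MAD of the first difference,
scaled) exceeds 0.08 mV or the trace leaves ±4 mV. The MAD makes the
estimate blind to QRS complexes, which occupy few samples per window.
Residual wander is the 0.05–0.55 Hz band RMS *after* filtering: none
< 0.04 mV ≤ mild < 0.25 mV ≤ significant.

`grade_quality()` maps, in order: no recognizable QRS → **3**; fraction
> 66% or significant wander → **2b**; fraction ≥ 33% (66% inclusive) or
mild wander → **2a**; fraction < 5% and no wander → **0**; otherwise
→ **1**. QRS recognizability requires 4–55 beats in 15 s with median peak
amplitude ≥ max(0.08 mV, 2.5 × global noise). P-wave recognizability is
scored (on clean windows) and reported, but does not itself worsen the
grade: absent P waves are a rhythm feature — AF and junctional records
would otherwise be systematically down-graded, which contradicts how a
physician grades *quality*. The grade is deterministic and monotone in the
artifact fraction.

## The AF decision

`classify_af()` implements the deployed rule: **AF ⇔ RR irregular ∧ P
absent**, with RR irregular = (CV ≥ τ_cv) ∨ (RMSSD/mean ≥ τ_rmssd) and P
absent = (p_score < τ_p). Defaults τ_cv = 0.12, τ_rmssd = 0.10, τ_p = 0.5
are conventional operating points; `calibrate_thresholds()` replaces them
by a deterministic grid search maximizing Youden's J on a labelled cohort
(ties to the first grid point in lexicographic order). APC/VPC detection is
deliberately absent from the output — the deployed algorithm removed it —
which is why ectopic rhythms with preserved P waves are the dominant
false-positive source for an RR-only rule and why the conjunction beats it:
on the default 500-subject cohort the RR-only rule produces ~35–38 false
positives, the conjunction rule 0–4. Grade-3 or too-few-beat records return
`UNGRADABLE` and are excluded from evaluation, as in the study.

## Evaluation and the published-table reconstruction

`build_confusion()` stratifies at age 65 (boundary in the lower stratum),
`rates()` computes sensitivity, specificity, PPV, NPV and prevalence, and
percentages are reported to one decimal with **ties rounded up**
(`round_half_up()`), matching the published formatting.

Interval methods were chosen by verifying which methods reproduce every
printed bound:

* **Sensitivity / specificity: Clopper–Pearson** exact intervals from beta
  quantiles (`exact_binomial_ci()`). These reproduce all six printed
  sensitivity/specificity intervals to one decimal (e.g. 21/22 →
  77.2–99.9%). A brute-force bisection on the exact binomial tails agrees
  with the beta-quantile form to 10⁻⁶ for all n ≤ 30 (this is a test).
* **PPV / NPV: standard logit (delta-method) intervals**
  (`predictive_value_ci()`), using
  $\mathrm{Var}[\mathrm{logit}(\widehat{PPV})] = \frac{1-se}{se\,n_1} +
  \frac{sp}{(1-sp)\,n_0}$ and its NPV analogue. Clopper–Pearson does *not*
  reproduce the printed predictive-value intervals (21/43 would give
  33.3–64.5 against the printed 38.5–59.3); the logit form reproduces all
  five, including the bare "100.0" NPV cell — when the false-negative
  count is zero the logit variance is infinite and no interval is defined,
  so the point estimate is printed alone.

The stratum false-positive counts were never printed; they are recovered
arithmetically from the printed stratum PPVs
(`recover_fp_from_ppv()`: tp = 4, PPV 36.4% ⇒ fp = 7; tp = 17, PPV 53.1%
⇒ fp = 15) and cross-checked against the printed overall 22. Subject-level
prevalence uses one record per resident (the first), reproducing the
922-resident denominator against 967 recordings.

## Problem sizes, determinism, numerics

The default experiment is 500 subjects (~520 recordings of 15 s at
500 Hz); unit tests use 60–120-subject cohorts and the acceptance runs use
the full 500. Every random draw flows from explicit seeds (cohort master
seed → per-record sub-seeds), so identical configurations give
byte-identical manifests and reports. Degenerate inputs have defined
behaviour throughout: zero-denominator rates are `NA` markers rather than
errors, an all-zero signal yields an empty peak list and grade 3, a
single-class calibration cohort is an error, and cutoffs at or above
Nyquist are rejected.

## Known limitations

* Sampling rate, amplitude resolution and electrode montage of the
  physical recorder are unknown; one lead-II-like channel at a
  configurable 500 Hz is assumed.
* The alternative SVM path of the deployed system is not reproduced (its
  features and kernel are unpublished); the classifier accepts a pluggable
  rule instead.
* Heavily corrupted recordings (> ~60% burst time) fall back to
  whole-record feature scoring; an AF record in that state can be missed,
  and occasionally is at the published grade mix (~0.8% of records are in
  that band).
* The grade distribution and satisfaction scores of the real campaign are
  generator targets, not reproducible outputs; the reconstruction stage
  reproduces only quantities that follow arithmetically from printed
  counts.
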