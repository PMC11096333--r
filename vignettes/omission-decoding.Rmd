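---
title: "Simulating, measuring and decoding auditory omission ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating, measuring and decoding auditory omission ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ospdecode)
```

## The scientific problem

When a listener knows a melody well, the brain predicts not just *that* a
note is coming but *which* note. A clean way to observe that prediction is
to omit an expected note: with no sound presented, any time-locked EEG
response (an omitted-stimulus potential, OSP) must be generated top-down.
Two empirical signatures are of interest:

1. **omission N1 (oN1)** — a frontocentral negative deflection near 100 ms
   after the expected onset, larger when the melodic context makes the note
   predictable (familiar melodies) than when it does not (unfamiliar,
   shuffled melodies);
2. **decodability of note identity** — if the omission response carries a
   note-specific prediction, a multivariate classifier should identify
   *which* of the four target notes (E, F, A, C) was omitted, above the 25%
   four-class chance level, and more accurately for familiar melodies.

`ospdecode` implements the full computational chain for this paradigm —
trial schedule, forward simulation, preprocessing, oN1 measurement,
time-resolved decoding and inference — so that every stage is testable
without access to the original recordings.

## The stimulus design

Four familiar melodies are each presented 20 times per condition. Across
the four melodies a single presentation contains 6 E, 6 F, 6 A and 7 C
target notes (each preceded by a G), so one condition comprises
20 × 25 = 500 target events, half of which are omitted: 60/60/60/70 = 250
omission trials per condition. Unfamiliar melodies are shuffled versions
that keep target positions and note counts.

Although omission is described as probabilistic (50%), the reported totals
are exact, so `build_schedule()` uses *balanced* assignment: within each
(condition, note) cell exactly `round(rate * n)` trials are omitted, in
seed-controlled random order. A rate that cannot balance exactly is rounded
and flagged in the schedule metadata.

Only the per-note totals of the published melody table are unambiguous in
our source; the split of each total across the four melodies is a package
assumption (shipped in `inst/extdata/melodies.json`) and is irrelevant to
every analysis, which conditions only on note identity.

## The forward model

`simulate_participant()` builds each omission epoch (−400…400 ms, 1000 Hz,
34 channels in 10-20 positions) as a sum of four parts:

* **oN1 component.** A fixed frontocentral topography (Gaussian on the
  scalp, normalized so the mean weight over the Fz/FC1/FC2/Cz ROI is 1)
  times a Hann-shaped temporal kernel centred at 109 ms with 25 ms
  half-width. The component shape is not specified by the phenomenon
  itself; any smooth unimodal kernel with a well-defined extremum works,
  and the Hann bump is chosen for compact support. Trial amplitude is
  normal around the participant's condition amplitude (`on1_within_sd`,
  default 1 µV — trial-to-trial variability is not constrained by published
  values and is an explicit knob).
* **Note-identity patterns.** One random unit-RMS spatial pattern per note
  per participant (fixed across trials, so decodability is a stable
  property of the participant), times a boxcar kernel over 50–90 ms, scaled
  by `note_pattern_amp` — 0.3 µV in the familiar condition and 0 in the
  unfamiliar condition by default, matching the hypothesis that only
  familiar melodies carry an identity-specific prediction.
* **Background noise.** Stationary 1/f (exponent 1) noise, spatially mixed
  across channels with a squared-exponential kernel over electrode distance
  (correlation length 0.35 head radii): spatially independent noise would
  make 34-channel decoding unrealistically easy. Synthesis uses a random
  cosine series band-limited to 45 Hz; content above the 25 Hz analysis
  low-pass would be removed anyway, so this is a speed simplification, not
  a modelling claim.
* **Artifacts.** A random `artifact_fraction` (default 3%, matching the
  reported average epoch retention) of epochs receive a ±200 µV decaying
  frontal transient, enough to trip the ±80 µV rejection screen. Ocular and
  cardiac components are deliberately not modelled: the pipeline's ICA slot
  is a documented no-op, and threshold rejection covers artifact handling.

Everything needed for recovery tests (true amplitudes, patterns, artifact
indices) is recorded as ground truth before any processing.

### Calibration of the population parameters

Population oN1 peak amplitudes default to −1.95 µV (familiar) and −1.37 µV
(unfamiliar) with between-participant SDs 1.1/1.0 µV. Two quantities are
not given directly by published summary statistics and were derived once,
before any acceptance test was written:

* `noise_sd = 6` µV per channel. With 250 trials this produces a
  per-participant measurement SD of ≈ 0.38 µV on the window-mean amplitude,
  so the *observable* per-condition SDs are √(1.1² + 0.38²) ≈ 1.16 and
  √(1.0² + 0.38²) ≈ 1.07 µV — matching the reported 1.17/0.98 µV.
* `on1_between_corr = 0.85`. The reported paired effect size dz ≈ −0.73
  implies var(diff) ≈ 0.63 µV² for the observed amplitudes. Subtracting the
  two measurement variances and solving
  var(diff) = σ²_f + σ²_u − 2ρσ_fσ_u gives ρ ≈ 0.85. A shared
  "responder" factor of this size is also physiologically expected — the
  same participant tends to produce large or small ERPs in both conditions.

With these two values the simulated study reproduces the reported
observable world (condition SDs and paired effect size) rather than just
the two means.

The default `note_pattern_amp = 0.3` µV is a qualitative choice: it yields
clearly above-chance but far-from-ceiling familiar-condition decoding, as
in the reported ≈30% window accuracy. (A 1 µV pattern already decodes near
ceiling once trials are block-averaged.) No acceptance criterion depends on
reproducing the printed accuracy, which is a property of the original
recordings.

## Preprocessing

The stage order is fixed and stamped into each epoch set's provenance:
band-pass filter → (ICA slot, skipped) → crop to −200…300 ms → ±80 µV
rejection → 200 ms baseline correction. Rejection is flag-based and
non-destructive. Whether the original ±80 µV screen ran before or after
baseline correction is not stated; reject-then-baseline is an assumption
(for threshold crossings the order is immaterial in practice, since the
artifact transients dwarf any baseline shift).

**Filter.** A zero-phase Hamming windowed-sinc band-pass, 0.5–25 Hz,
applied with mirror padding via FFT; the symmetric kernel has no group
delay. The kernel length follows the standard Hamming rule
L ≈ 3.3/(Δf/fs). The transition width Δf is the one genuinely free design
choice: continuous-recording pipelines use a fraction of the low edge
(giving multi-thousand-tap kernels), which cannot be supported by an
800 ms epoch. The default Δf = 6.25 Hz — 25% of the *upper* passband edge —
gives a 529-tap kernel, the sharpest design whose padding fits the
simulated epoch. Consequences, verified by the test suite against the
directly evaluated transfer function: an exact null at 0 Hz (the epoch
high-pass only needs to remove DC/drift), gain within 1% at 10 Hz, ≥53 dB
attenuation at 50 Hz, and a gradual low-frequency roll-on below ≈4 Hz.

**Inclusion gate.** A participant enters decoding only if every note class
retains ≥50 artifact-free trials *and* ≥80% of its scheduled trials (the
stricter reading of "less than 80% or 50 trials"); the ERP analysis is not
gated.

## oN1 measurement

Condition grand means over the frontocentral ROI are averaged together;
the most negative sample within 50–110 ms is the oN1 peak (ties break to
the earliest sample; a peak on the search boundary raises an `edge` flag);
the measurement window is peak ±10 ms with inclusive endpoints (99–119 ms
spans 21 samples at 1000 Hz). Amplitude is the window mean.

Because the window averages the Hann kernel and the filter shapes it, a
true peak amplitude A appears as ≈0.75·A in the measured window mean.
`on1_measurement_gain()` computes this factor exactly by pushing a
noiseless unit epoch through the identical pipeline; recovery tests divide
by it rather than tolerating a fudge factor.

## Decoding

Per time point and condition, a One-vs-Rest linear-margin classifier
(hinge-loss linear SVM, cost 1, dual coordinate descent in compiled code)
is trained on the 34 raw channel voltages. Threefold cross-validation is
repeated 20 times; within each iteration classes are equalized (the
70-trial C class is subsampled to 60), trials of each class are randomly
split into three blocks, and — the most consequential open choice — trials
within each class × block are *averaged into a single observation* before
classification (`block_averaging = TRUE`), following the participant-based
ERP decoding approach this paradigm cites. A single-trial mode is provided
for comparison. Ties between decision values go to the earliest class in
E, F, A, C order. Feature standardization is off by default (raw µV) and
available as a flag; neither choice is claimed to be the original one.
Decoding runs over −200…300 ms at every sample by default, with a
`decimation_ms` setting for desk-scale runs.

## Statistics

* `paired_t_dz()` / `one_sample_t_dz()`: standard t tests reporting
  dz = mean(diff)/sd(diff), with the identity dz = t/√n held to numerical
  precision.
* `jzs_bf10()`: the default JZS Bayes factor for the one-sample/paired
  design — Cauchy(0, 0.707) prior on the standardized effect, evaluated by
  adaptive quadrature of the scale-mixture integral (relative tolerance
  1e-8). BF01 = 1/BF10 is returned alongside.
* `cluster_permutation()`: time-axis cluster-based permutation test.
  Pointwise paired t; cluster-forming threshold is the two-tailed critical
  t at α = 0.05 (unstated in our source; this is the field-standard
  choice, and it is configurable); clusters are maximal same-sign
  suprathreshold runs summarized by t_sum; the null is the maximum |t_sum|
  under per-participant sign flips, with the +1-smoothed p so that
  p ∈ [1/(N+1), 1]. One-tailed variants restrict the reported clusters.
* `power_sample_size()`: smallest n whose noncentral-t power reaches the
  target (dz = 0.66, α = 0.05, power 0.80 → n = 21).

## What a green test establishes — and what it does not

The synthetic world contains exactly the structure the analysis assumes:
a single smooth component with a fixed topography, stationary Gaussian
noise, patterns strictly confined to 50–90 ms, and artifacts that are
always threshold-detectable. Green acceptance tests therefore establish
that the *pipeline* is correct and calibrated (unbiased amplitude
recovery, chance-level decoding without signal, localized clusters with
signal, nominal family-wise error), not that the published biological
effect sizes would replicate. Real EEG adds non-stationarity, ocular and
muscle components that survive thresholding, latency jitter across trials
and participants, and reference/montage imperfections that this generator
deliberately omits. The printed group results (−1.95/−1.37 µV, 30.2%/24.0%
accuracy, cluster 58–83 ms with t_sum = 87.11) depend on the original
recordings and are treated as regression anchors only where they are pure
functions of printed statistics (dz, BF10, power n).

## Numerical and degenerate-input choices

* Argmin ties break to the earliest sample; an edge-located peak is
  flagged, not rejected (the stated window rule is applied literally even
  though the 109 ms peak sits 1 ms inside the predetermined 50–110 ms
  search interval).
* Zero-variance differences make t undefined: an error, not NaN.
* The JZS integrand is evaluated as a ratio in log space so large |t|
  cannot overflow; non-convergent quadrature is an error with the
  integrator's diagnostic.
* Exactly balanced omission requires `rate * cell` integral; otherwise the
  count is rounded and the schedule flagged `balanced = FALSE`.
* An epoch too short for the requested FIR kernel raises an error naming
  the required padding instead of silently shortening the kernel.
* SVM decision ties go to the lowest class index (fixed E, F, A, C order).

## Reproducibility and scale

Every stochastic routine takes an explicit seed; `run_pipeline()` derives
all stage seeds from one master seed and stamps each output with the
config hash, so a rerun is byte-identical. The `paper_faithful` preset
pins the full-scale analysis (25 participants, 250 trials/condition,
3-fold × 20 iterations at every millisecond, 10,000 permutations);
`paper_faithful_small` keeps every methodological setting and shrinks only
the sizes. The acceptance test suite likewise scales seed counts and
decoding iterations down to fit a single-CPU budget — scale reductions are
stated in the test file and never alter generator parameters, thresholds
or tolerances.
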