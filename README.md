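# ospdecode

Simulation, measurement and decoding of auditory **omission ERPs** in
multichannel EEG.

When an expected note of a melody is unexpectedly silenced, the EEG still
shows a response time-locked to the missing onset — an omitted-stimulus
potential (OSP). Because nothing was played, that response is purely
top-down: a prediction-error signal. Two questions follow for anyone
studying musical prediction:

* Is the **omission N1 (oN1)** — the frontocentral negativity near 100 ms —
  larger when the melody is familiar (the note is predictable) than when it
  is unfamiliar?
* Does the omission response carry the **identity** of the missing note?
  If so, a multivariate classifier should label the four possible target
  notes (E, F, A, C) above the 25% chance level from the 34-channel
  voltage pattern, time point by time point.

`ospdecode` implements the complete analysis chain for this paradigm, with
a forward simulator standing in for recordings so every stage is testable:

| module | what it does |
|---|---|
| `build_schedule()` | trial schedule: 4 melodies × 20 presentations per condition, note totals 6/6/6/7, exactly half of each (condition, note) cell omitted → 250 omission trials per condition |
| `simulate_participant()` / `simulate_cohort()` | 34-channel, 1000 Hz epochs: frontocentral oN1 (Hann bump at 109 ms), per-note spatial patterns at 50–90 ms (familiar only), spatially correlated 1/f noise, threshold-detectable artifacts; full ground-truth bookkeeping |
| `preprocess_epochs()` | zero-phase Hamming windowed-sinc 0.5–25 Hz band-pass → crop −200…300 ms → ±80 µV rejection (flag-based) → 200 ms baseline; `check_inclusion()` gates decoding at ≥50 trials and ≥80% retention per class |
| `define_on1_window()` / `mean_amplitude()` | data-derived measurement window: most negative point of the combined grand mean in 50–110 ms, ±10 ms (→ 99–119 ms), inclusive endpoints |
| `decode_timecourse()` | per-time-point 4-class One-vs-Rest linear SVM, 3-fold CV × 20 iterations, class equalization and within-block trial averaging |
| `paired_t_dz()`, `jzs_bf10()`, `cluster_permutation()`, `power_sample_size()` | t tests with dz = t/√n, default JZS Bayes factors (Cauchy r = 0.707), time-axis cluster permutation with sign-flip max-t_sum null, noncentral-t power analysis |
| `run_pipeline()` | end-to-end run from a YAML/JSON config with one master seed, provenance-stamped outputs |

## Worked example

The `paper_faithful_small` preset keeps every methodological setting of the
full design and shrinks only the sizes (8 participants, decoding every
10 ms with 5 iterations, 500 permutations):

```r
library(ospdecode)
rep <- run_pipeline(default_run_config("paper_faithful_small", seed = 42),
                    out_dir = "out")
print(rep)
#> oN1 window 99-119 ms (peak 109 ms)
#> oN1 mean familiar -1.68 uV, unfamiliar -1.19 uV; t(7) = -2.31, p = 0.05445, dz = -0.82, BF10 = 1.78
#> decoding: 8 participants included, 3 cluster(s)
#>   start_ms end_ms     t_sum     p_perm
#> 1     -110   -110 -3.289100 0.61477046
#> 2       60     80 11.144839 0.03193613
#> 3      210    220  5.108091 0.40518962
#> power analysis: n = 21 for dz = 0.66
```

Reading the output:

* the combined grand average peaks at 109 ms, so amplitudes are measured
  over **99–119 ms** — the window rule recovering the generator's truth;
* familiar omissions are more negative (−1.68 µV) than unfamiliar ones
  (−1.19 µV); at this reduced n = 8 the paired test is only borderline
  (p ≈ 0.054) — the full 25-participant preset has ≈94% power for the
  configured effect;
* the only *significant* decoding cluster (p ≈ 0.032, permutation-corrected)
  sits at **60–80 ms**, inside the 50–90 ms interval where the generator
  injected note-identity patterns; the flanking clusters are the expected
  false-positive candidates that the max-statistic correction rejects;
* the power analysis reproduces the predetermined sample size, n = 21 for
  dz = 0.66 at α = 0.05 and power 0.80.

Outputs in `out/`: `schedule.csv`, `amplitudes.csv` (participant ×
condition window means), grand-average CSVs, `accuracy.csv` (participant ×
condition × time), `stat_report.json`, `run_info.json` — each stamped with
the package version, config hash and master seed; a rerun with the same
seed is byte-identical.

A command-line entry point with the same behaviour is installed at
`inst/cli/ospdecode.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ospdecode.R", package="ospdecode"))')" \
  --preset paper_faithful_small --out out --seed 42
```

## Further reading

`vignettes/omission-decoding.Rmd` documents the forward model and its
calibration, every tunable parameter with units and defaults, the open
design choices (filter transition width, block averaging, cluster-forming
threshold, tie-breaks) and the limits of what the synthetic world can
establish.
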