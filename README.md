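# strainpost

Post-processing of speckle-tracking echocardiography deformation curves.

Commercial speckle-tracking packages compute myocardial strain curves from
ultrasound images but expose only a fixed set of derived parameters. Many
of them can, however, export the underlying curves ("raw data") as plain
text. `strainpost` works on those exports: it segments one cardiac cycle
into its six mechanical phases, detects per-segment peak systolic strain,
computes Global Longitudinal Strain (GLS), derives strain rate, and runs
the paired method-agreement battery used to validate one GLS pipeline
against another. It is aimed at echocardiography researchers who need
parameters, phase-resolved views or multi-chamber displays that their
vendor software does not provide.

## The model

**Phases.** With the valve events (MVC, AVO, AVC, MVO) and the ECG
landmarks (first QRS onset `qrs1`, P-wave onset, second QRS onset `qrs2`),
the cycle `[qrs1, qrs2)` is partitioned into six contiguous half-open
intervals:

| phase | meaning | interval |
|-------|---------|----------|
| EMC  | electromechanical coupling | `[qrs1, MVC)` |
| IVC  | isovolumic contraction     | `[MVC, AVO)` |
| Ejec | ejection                   | `[AVO, AVC)` |
| IVR  | isovolumic relaxation      | `[AVC, MVO)` |
| E    | early filling (incl. diastasis) | `[MVO, P onset)` |
| A    | atrial contraction         | `[P onset, qrs2)` |

**Peak systolic strain.** For each segment curve `s(t)` the systolic
search window is `[qrs1, AVC]`. Two selection rules are implemented:

* `min` — the most negative sample in the window (the least positive one
  for exclusively positive curves);
* `pos75` — the rule used by GE EchoPAC: with `N = min` and `P = max`
  over the window, select `P` when `P > 0.75·|N|`, otherwise `N`.

The rules diverge on dyssynchronous (LBBB-like) curves, where early
systolic stretching produces large positive peaks.

**GLS** is the arithmetic mean of the 18 segmental peaks of the AHA
18-segment left-ventricular model (6 segments from each apical view; the
4-chamber acquisition is the time reference and the other views are
linearly time-rescaled and resampled onto its grid).

**Method agreement.** For paired GLS series `a` (reference) and `b`
(candidate), with `d = a − b`: Shapiro–Wilk normality (with Q-Q data) on
`a`, `b`, `d`; Pearson correlation if both marginals are normal, else
Spearman; paired *t* test if `d` is normal, else Wilcoxon signed rank;
Bland–Altman bias `mean(d)` and limits of agreement `bias ± 1.96·SD(d)`.
Equivalence requires `r ≥ 0.95`, test `p > 0.05`, `|bias| ≤ 1 %` and
dispersion (`1.96·SD(d)`) `≤ 2 %`.

## Worked example

Simulate a study with known ground truth, write it as canonical trace
files, and run the pipeline (the same flow is available from the shell via
`inst/cli/strainpost.R`, subcommands `run`, `simulate`,
`validate-pairs`):

```r
library(strainpost)

ev <- event_timing(qrs1 = 0, mvc = 30, avo = 80, avc = 380,
                   mvo = 460, p_onset = 700, qrs2 = 850)
segment_phases(ev)
#> Cardiac cycle phases (half-open intervals, ms):
#>   EMC  start     0.0  duration    30.0
#>   IVC  start    30.0  duration    50.0
#>   Ejec start    80.0  duration   300.0
#>   IVR  start   380.0  duration    80.0
#>   E    start   460.0  duration   240.0
#>   A    start   700.0  duration   150.0
#>   cycle length 850.0 ms

set.seed(4)
spec <- synthetic_study_spec(events = ev, peaks = runif(18, -24, -10))
write_synthetic_study(spec, "sim1", rv_peaks = runif(6, -28, -16))
mean(spec$peaks)          # ground-truth GLS
#> [1] -16.6787

res <- run_pipeline("sim1", events = ev, option = 4,
                    exam_id = "E1", out_dir = "out1", quiet = TRUE)
res$gls$gls
#> [1] -16.6787
```

The per-segment peaks, phase times and QC flags are printed as stable
`key: value` lines and written to `out1/E1_report.txt`; the figure
`out1/E1_curves.png` shows the 18 LV and 6 RV curves and the ECG with
MVC/AVO/AVC/MVO markers.

The packaged 48-subject paired-GLS series (EchoPAC vs. the window-minimum
pipeline) runs through the full agreement battery:

```r
validate_gls_pairs()
#> n: 48
#> normality a: W = 0.9281, p = 0.0058 (non-normal)
#> normality b: W = 0.9314, p = 0.0077 (non-normal)
#> normality diff: W = 0.9128, p = 0.0017 (non-normal)
#> correlation: spearman r = 0.9850 (0.99)
#> paired test: wilcoxon p = 0.3833
#> bias: -0.0979
#> sd diff: 0.7049
#> loa: [-1.4795, 1.2836]
#> dispersion: 1.3816
#> correlation_ok: TRUE
#> test_ok: TRUE
#> bias_ok: TRUE
#> dispersion_ok: TRUE
#> equivalent: TRUE
```

Both methods are equivalent under all four criteria: Spearman r rounds to
0.99, the paired test accepts the null of zero mean difference, the bias
is about 0.1 % and the limits of agreement span about ±1.4 %. The
`subject19 = "corrected"` variant (see `?gls_validation_pairs` for the
typographic ambiguity in that row) makes the differences pass normality,
so the gate selects the paired *t* test (p = 0.674). See the vignette
(`vignettes/strain-postprocessing.Rmd`) for the methods discussion.

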