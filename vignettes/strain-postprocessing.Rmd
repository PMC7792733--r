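---
title: "Methods: phase segmentation, peak detection and method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase segmentation, peak detection and method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpost)
```

`strainpost` post-processes time-sampled myocardial deformation curves —
longitudinal strain in percent and strain rate in 1/s — exported as plain
text by speckle-tracking echocardiography software. This vignette
explains the models and conventions the package commits to, why the
tunable parameters have the defaults they have, what the synthetic-signal
generator does and does not emulate, and the numerical choices made where
the problem left room.

## The trace model and the export dialect

A `strain_trace` is a strictly increasing time axis in milliseconds with
one curve per myocardial segment, with the time origin fixed at the onset
of the first QRS complex of the selected cycle. Left-ventricular studies
follow the AHA 18-segment model: six segments per apical view (4-, 3- and
2-chamber), merged into one 18-segment trace. Because heart rate differs
slightly between the three acquisitions, the 4-chamber record is the time
reference: `align_views()` rescales the other views' time axes linearly
by the ratio of cycle lengths and resamples their curves onto the
reference grid by linear interpolation. Linear scaling plus linear
interpolation is the minimal defensible choice: cycle-length differences
across views of one exam are a few percent, and any subtler time warping
would impose a physiological model the data cannot support. A ratio
outside [0.5, 2] is rejected as a wrong-cycle selection.

Vendor export formats are proprietary and undocumented, so the package
defines its own canonical dialect (tab-separated, `# key: value`
metadata, a `time_ms` column, one column per segment, an optional `ecg`
column, `.` decimals, full double precision) and a tolerant reader that
also accepts decimal commas, semicolon or whitespace delimiters and
arbitrary column order — enough to ingest typical European-locale
exports after trivial reshaping. Read-after-write is exact.

## Phase segmentation

Six mechanical phases partition the cycle `[qrs1, qrs2)`, bounded by the
named events in their physiological order: QRS onset → MVC → AVO → AVC →
MVO → P onset → second QRS onset, giving EMC, IVC, Ejec, IVR, E and A.
Three conventions are deliberate:

* **Half-open intervals** `[start, end)`, so every sample belongs to
  exactly one phase and the six durations sum exactly to the cycle
  length — the partition property is tested, not assumed.
* **`qrs1 = mvc` is allowed** as a degenerate zero-length EMC; all later
  orderings are strict.
* **The E/A boundary sits at P-wave onset**, the only intra-diastolic
  ECG landmark collected; diastasis is merged into E. Any finer split
  would require a landmark (end of the E wave) the inputs do not carry.

Landmarks arrive from a config file or function arguments, not from
interactive clicks, so runs are reproducible; `validate_landmarks()`
enforces ordering and that the marks lie inside the ECG span. When an
exam carries repeated event registrations,
`check_event_timing_consistency()` flags any event whose registrations
spread by more than 10 ms — the exclusion rule applied when the pipeline
was validated against a commercial package.

## Peak systolic strain and GLS

The systolic search window runs from the first QRS onset to aortic valve
closure; since the window bounds rarely coincide with sample times, the
sample nearest each bound is included. Two selection rules are provided:

* **`min`** (the package's native rule): the window minimum, even when
  the whole curve is positive — then the least positive value is taken.
  Ties break to the earliest time.
* **`pos75`** (the rule of GE EchoPAC): the positive window maximum `P`
  is selected when it *exceeds* 75% of the magnitude of the negative
  minimum `N` (strict inequality — "exceeds" is read literally),
  otherwise `N`; with no negative values in the window, `P`.

Peaks are taken on the sample grid; no sub-sample interpolation is
attempted, because exported curves are already temporally filtered and
the flat systolic plateau makes sub-sample refinement cosmetic. No
manual peak adjustment is offered: adjustments would reintroduce the
operator variability the pipeline exists to remove.

GLS is the arithmetic mean of the 18 segmental peaks. Segments judged
inadequate can be excluded explicitly; excluding more than two raises a
QC flag, mirroring the exclusion threshold used in validation. Strain
rate is derived from strain by central finite differences of fractional
strain against time in seconds (divided differences on non-uniform
grids, one-sided at the ends), second-order accurate on uniform grids;
smoothing before differentiation is available but off by default, since
the exports are filtered upstream and double smoothing biases peaks.

## The method-agreement battery

`compare_methods()` reproduces a normality-gated comparison protocol for
paired measurements `a` (reference) and `b` (candidate), differences
oriented `d = a − b`:

1. Shapiro–Wilk on `a`, `b`, `d` at α = 0.05, each with Q-Q data at
   plotting positions `(i − 0.5)/n` and a reference line through the
   quartile points.
2. Pearson correlation iff both marginals pass normality, Spearman
   otherwise.
3. Paired *t* iff `d` passes normality, Wilcoxon signed rank otherwise.
   The Wilcoxon uses the normal approximation with continuity correction
   above 25 non-zero differences and the exact distribution below; zero
   differences are dropped (the standard signed-rank convention; the
   protocol itself does not specify these details).
4. Bland–Altman: bias = `mean(d)`, limits of agreement
   `bias ± 1.96·SD(d)`.

The equivalence verdict applies four criteria: correlation ≥ 0.95
(applied to the coefficient rounded to two decimals, the precision at
which it is reported), test p > 0.05, |bias| ≤ 1 % and dispersion ≤ 2 %.
"Dispersion" is interpreted as the half-width of the limits of
agreement, `1.96·SD(d)` — the quantity a Bland–Altman plot displays as
the distance from bias to either limit; the raw SD is reported alongside
so the alternative reading (dispersion = SD) can be checked directly.
Thresholds are absolute, in % GLS units, because GLS is negative-signed.
Degenerate inputs are handled explicitly: identical series produce a
warning and p = 1 (equivalence holds trivially); constant non-zero
differences produce p = 0.

### The packaged 48-subject series

The package ships a 48-subject paired-GLS table (EchoPAC versus the
window-minimum pipeline) used by `validate_gls_pairs()`. One row is
typographically ambiguous in the source listing: subject 19 prints as a
garbled `-19,500-16,68`. The fixture keeps the literal reading
(−19.50, −16.68) by default. Under that reading the differences fail
Shapiro–Wilk (p = 0.0017), the gate selects Wilcoxon (p = 0.383) and
Spearman r = 0.985; all four equivalence criteria still hold. Under the
single-digit repair (−19.50, −19.68), selectable with
`subject19 = "corrected"`, the battery becomes internally coherent with
the series' published summary: the differences pass normality
(p = 0.129), the paired *t* is selected (p = 0.674), and Spearman
r = 0.992. The repair is adopted only as an explicit option — the data
as printed remain the default — but the coherence of the corrected
battery is strong evidence that the analyzed data contained the repaired
value and the listing contains a typo.

## The synthetic generator

`generate_strain_cycle()` produces phase-structured curves with known
ground truth so every stage is testable without clinical data. Per
segment, the curve is a chain of half-cosine arcs through control points
at the phase boundaries: zero at the QRS onset, an optional positive
early-systolic bulge peaking at MVC (emulating the basal stretching of
left-bundle-branch-block dyssynchrony, which is what makes the two peak
rules disagree), monotone descent to the target peak exactly at AVC, a
partial early-diastolic recovery, a small atrial deflection, and return
to zero at the cycle end. Event times are inserted into the sampling
grid, so with zero noise the detected window minimum equals the target
peak exactly, for all 18 segments.

Defaults describe a normal adult at ~70 bpm: an 850 ms cycle with
MVC 30, AVO 80, AVC 380, MVO 460 and P onset 700 ms after the QRS onset,
5 ms sampling, and per-segment peaks of −18 % (a normal GLS). These are
the conditions under which the recovery properties are stated and
tested.

Measurement noise is modelled as a *smooth* correlated Gaussian process:
white noise smoothed with a Gaussian kernel (30 ms correlation time) and
renormalized to the requested marginal SD. This mirrors how
speckle-tracking traces actually look — vendors filter temporally, so
sample-to-sample noise is strongly correlated. The choice matters for
validity, not convenience: a window-minimum detector applied to
white-noise-corrupted curves is biased downward by roughly the noise SD
times the expected extreme of the many effectively independent samples
near the flat systolic valley (about −0.6 % at a 0.5 % noise SD on the
default grid), a bias real filtered traces do not exhibit. With smooth
noise the detector is nearly unbiased and the GLS error over 18
segments behaves like an average of 18 weakly biased draws; over 50
simulated studies at 0.5 % noise the mean absolute GLS error is about
0.1 % (individual studies can exceed 0.2 %, as the ~0.12 % per-study SD
implies). What the generator does **not** emulate: speckle-tracking
drift, tracking dropout, inter-vendor filtering differences, or
physiological beat-to-beat variability — so passing recovery tests shows
the post-processing is correct, not that any vendor's tracking is.

`generate_paired_gls()` simulates a method comparison directly:
`a ~ N(μ, spread)`, `b = a − bias + N(0, sd_diff)`, so the differences
have mean `bias` and SD `sd_diff` by construction; estimated bias and
dispersion converge to the generating values at the Monte-Carlo rate.

## The pipeline and its problem sizes

`run_pipeline()` reproduces the interactive tool's flow
non-interactively: read per-view files → align → validate landmarks →
segment phases → peaks/GLS → stable `key: value` terminal report →
multi-panel figure with MVC/AVO/AVC/MVO markers. Six view options select
the panels; option 6 ingests simulated strain without ECG (e.g. output
of the CircAdapt circulation model), skips phase separation entirely and
flags peaks as "unphased". Unlike the interactive original, options can
be changed without re-parsing: the aligned 18-segment trace is cached as
a canonical file and reused. Reports carry no timestamps, so identical
configurations yield byte-identical output.

The test suite and the acceptance script run entirely on synthetic
studies of one cycle at 5 ms sampling (about 190 samples × 18 segments),
50-study noise ensembles, 100-curve rule checks, 1000-cycle partition
checks, and a 10 000-pair simulated method comparison — sizes chosen so
the full battery stays a desk-scale computation while keeping
Monte-Carlo error well below the tolerances being asserted.

## Known limitations

* Phase boundaries are fixed by the seven supplied event times; no
  automatic QRS/P detection or valve-event detection is attempted.
* Atrial strain conventions (reservoir/conduit/booster) are not
  implemented; LA/RA traces are displayed, not decomposed.
* Bland–Altman confidence intervals for the limits of agreement and
  proportional-bias regression are out of scope.
* The agreement battery requires 3–5000 pairs (the Shapiro–Wilk range);
  larger simulated series are summarized through the Bland–Altman
  statistics directly.
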