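---
title: "Methods: stance-phase M-curve analysis and the synthetic-gait generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stance-phase M-curve analysis and the synthetic-gait generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stancecurves)
```

## The measurement problem

Pressure-sensing insoles report the total vertical ground-reaction force
under each foot at a nominal 100 Hz. During level walking the force over a
stance phase traces the familiar M-curve: a weight-acceptance peak (Fz2),
a midstance minimum (Fz3) and a push-off peak (Fz4). Walking on a slope
redistributes load between heel strike and push-off, so the shape of the
M-curve carries information about the surface grade: downhill walking
raises the first peak and steepens loading; uphill walking raises the
second peak and steepens unloading. The package extracts nine scalar
descriptors of each stance curve and quantifies their dependence on
treadmill grade between −20% and +20%.

Compared with force plates or instrumented treadmills, insoles sample
slowly and noisily; the pipeline's design choices — spline resampling,
Gaussian disambiguation, a strict rejection cascade — all exist to make
extremum identification reliable under those conditions.

## Processing model

**Stance segmentation.** A stance is a maximal run of samples with force
strictly above 30 N. Runs of up to 3 consecutive "missing values" — either
absent timestamps (dropped samples) or sub-threshold readings, which the
segmentation treats identically — do not terminate an event; four or more
do. Events are trimmed so that the first and last samples are
above-threshold, and events shorter than 300 ms or longer than 2000 ms
(first sample to last sample, both bounds inclusive) are discarded with a
logged reason. "Above 30 N" is read literally: a reading of exactly 30 N
counts as below.

**Normalization.** Forces are scaled to fractions of body weight
(`force_N / (weight_kg × 9.81)`; the reference tables print e.g. 1.20 for
a peak 20% above body weight, so fractions are the native unit). The time
axis is normalized by fitting a natural cubic spline — zero second
derivative at both ends — to the event's raw `(timestamp, force)` samples
and evaluating it at 100 equidistant times spanning the event inclusively:
index `j` (0-based) is stance fraction `j/99`. Dropped samples are bridged
by the spline naturally; tolerated sub-threshold samples act as ordinary
knots; negative spline excursions are clamped to zero. Events with fewer
than four samples (no cubic spline) are rejected, not errors.

**Smoothing for localization only.** A Gaussian kernel with σ = 3 and
size 7 (weights ∝ exp(−k²/18), k = −3…3, normalized to sum 1; truncated
and renormalized at the curve boundaries so constants are preserved) is
applied to the normalized curve. The smoothed copy is used *only* to
locate extremum indices; all reported values are read from the unsmoothed
curve at those indices, so no amplitude is lost to smoothing. Whether
smoothing precedes or follows the resampling is ambiguous in principle;
the package smooths the 100-sample curve, which keeps the two copies on a
common index axis so the located indices can be re-applied directly.

**Candidate cascade.** Strict local extrema of the smoothed curve are the
candidates. If they are not already exactly two maxima and one minimum,
four strategies apply in order, each only while ambiguity remains:
(1) candidates within the first or last 10 indices are eliminated;
(2) same-polarity candidates chained by index gaps ≤ 5 form a pool of
which only the highest maximum / lowest minimum survives (ties: earlier
index); (3) candidates that are not strictly monotone on both flanks over
5 indices are eliminated; (4) if the monotony check overshot (fewer than
two maxima or no minimum left), its casualties are reinstated in
descending order of achieved monotony distance (ties: earlier index).
Stances that still lack exactly two maxima and one minimum are rejected
(`candidate_count`), as are — by a documented, toggleable convention —
stances whose minimum does not lie between the maxima (`ordering`).
Monotony distances truncated by the curve boundary are capped at the
available length. The cascade involves no randomness.

**Parameters.** With 0-based indices `i2 < i3 < i4` for Fz2/Fz3/Fz4:
`fmean_stance` is the mean of all 100 samples; `fmean_load` the mean over
`[0, i2]`, `fmean_mid` over `[i2, i4]`, `fmean_unload` over `[i4, 99]`,
all windows inclusive at both ends (the definitions say "between X and Y"
without a convention; inclusive ends are symmetric and shift results well
under 1%). The loading slope is the line from index 0 to the first sample
at/above 80% of Fz2; the unloading slope the line from the first
post-`i4` sample below 80% of Fz4 to index 99. Force enters the slopes in
*percent* body weight — the only scaling under which peaks around 1.2
fractions coexist with slopes of magnitude 5–11 per percent of stance
duration, as the reference tables print. Slopes are undefined (NA, and
flagged) when the crossing happens at the first sample, never happens, or
happens only at the last sample; the stance's other parameters are kept.

**Aggregation.** Both feet are pooled. The default pooling averages each
participant's steps first and then across participants (matching
"averaged over all participants"); direct step pooling is available as an
option since the provenance of published SDs is ambiguous. Per-grade
means are divided by the 0%-grade mean (×100) to give percent of
horizontal walking — plain division, so a more negative unloading slope
maps above 100% — and each parameter's nine-point series is fitted by
ordinary least squares on grade. The per-step regression ANOVA fits each
raw parameter on grade over all accepted steps; significance is the
conventional 0.05, with no multiple-testing correction (none is applied
in the reference analysis).

## The synthetic-gait generator

No raw recordings are distributed with the reference study, so the
generator is the package's test bed: it emits raw force series whose
*pipeline-extracted* parameters reproduce the published per-grade means.
Its defaults encode the study conditions: nine grades from −20% to +20%,
40 participants, body weights 55–110 kg, one minute of walking ≈ 50
stances per foot and grade at 4 km/h, stance durations 620–780 ms, swing
gaps 350–450 ms, sensor noise 0.02 body weights, occasional dropped
samples.

**Draw model.** Between-step variance is dominated by who is walking, so
each participant draws a shared amplitude factor (normal, cv 0.22–0.24,
truncated below at 0.7 and standardized to unit mean over the sampled
cohort) that scales all three extrema, times a small independent per-step
jitter (cv 0.06). Sharing the factor preserves the M-shape almost surely —
independent draws at the published SDs would violate it for roughly a
fifth of steps and bias the means once truncated — and reproduces
realistic between-participant spread. The truncation reflects the
pipeline's validity domain: amplitudes below ~0.7 put the second-peak
prominence under the sensor noise floor, where the cascade rejects most
events anyway. Window-mean and slope targets scale with the drawn extrema
so their population means stay on target.

**Template family.** Each stance is a shape-preserving cubic Hermite
interpolant (Fritsch–Butland derivatives) through anchors at the stance
boundaries (force 0.08 body weights, safely above 30 N for all weights),
the three extrema, and auxiliary points on each flank. Monotone
interpolation guarantees extrema exactly at the anchors and nowhere else.
Three shape handles — the loading ramp height, the valley width, the
unloading tail height — are solved per step (bracketed secant) so that
the loading, midstance and unloading window means of the *discretised*
template, measured at the extremum indices that a noise-free pipeline run
(smoothing + strict extrema) detects on it, equal the targets; the solve
iterates until the detected indices are the ones it calibrated against.
Targets outside the achievable shape range (a few percent of draws at the
grade extremes) are clamped to the nearest achievable value.

**Crossing geometry.** The slope definitions read the first sample at a
threshold crossing, which quantizes the crossing run to whole indices. The
generator therefore places each 80% crossing on an integer run, drawn from
the two integers bracketing the target run with probabilities chosen so
that the expected reciprocal run — and hence the expected extracted
slope — matches the target. A short steep "shoulder" before each crossing
keeps the crossing index insensitive to sensor noise, and the first
samples after the unloading crossing follow the intended slope line so a
noise-shifted crossing index still reads a value near that line.

**Timing conventions.** Extremum timing is not part of the reference
tables. The first peak sits near 25% and the valley at 54% of stance; the
second peak at 79–83% depending on grade, jittered ±0.05 per step. Two
constraints pin these choices: the 80%-of-Fz4 unloading crossing implied
by the slope targets sits near 88% of stance, so the second peak must be
late enough for its fall to fit; and the whole-stance mean is an identity
in the three window means, the extrema and the window boundaries, so the
per-grade `t` values are solved to reproduce the flat `fmean_stance`
profile of the reference table. The slightly later valley steepens the
valley-to-second-peak climb, which halves noise-induced candidate
ambiguity at the steep downhill grades.

**Ground truth.** Every emitted stance records the values a noise-free
pipeline extracts from its clean template — not the nominal draw — so
closed-loop comparisons measure exactly the effect of noise, dropped
samples and segmentation, with no constructional residue. Stance bounds
are aligned to the 10 ms sampling grid, making the noise-free loop exact.

**What the generator does not emulate.** White, homoscedastic sensor
noise rather than the correlated, load-dependent noise of real sensors;
no per-sensor spatial structure; no fatigue, footwear, cadence or
speed effects; smooth single-family curve shapes rather than the full
morphological variety of real gait (flat feet, double strikes,
pathological curves). Passing closed-loop tests therefore demonstrates
that the *pipeline* is faithful to its definitions and robust at the
stated noise level — not that it handles every real-world irregularity;
the rejection cascade is the designed safety valve for those.

## Numerical choices and degenerate inputs

* Threshold comparisons are strict (`> 30 N`, `≥ 0.8·Fz2`, `< 0.8·Fz4`)
  per the parameter definitions; all constants are surfaced in
  `stance_defaults()` and overridable, with deviations recorded in the
  `run_pipeline()` manifest.
* Pool clustering is single-linkage on index gaps; all tie-breaks
  (pool value ties, grace distance ties) resolve to the earlier index,
  making the cascade order-independent and deterministic.
* The spline is fitted to true timestamps; uniform time shifts leave the
  normalized curve unchanged to machine precision.
* Events with <4 samples, slopes with degenerate crossings, grades with
  zero accepted steps, and zero-variance regression responses (R² defined
  as 0) are all handled as logged rejections/flags, not errors.
* Natural end conditions make the spline exact on linear data; on curved
  data the boundary mismatch decays geometrically away from the ends
  (about three orders of magnitude within a quarter of the stance), which
  the tests pin against an independently coded tridiagonal solver.

## Problem sizes used by the tests

The closed-loop and significance checks run one shared session of 40
participants × 2 feet × 9 grades × 25 steps (18,000 stances, ~90 s to
generate and ~20 s to process); property suites use 1000 random masks for
the segmentation oracle and 50-replicate sweeps for the smoothing
invariants. The acceptance script simulates 600 horizontal stances.
These sizes give sub-percent standard errors on every compared mean while
keeping a full run in a few minutes.

## Known limitations

* The ordering requirement (minimum between the maxima) is a convention;
  curves whose cascade survivors are misordered are rejected rather than
  re-searched. The flag `require_ordering = FALSE` accepts them.
* Re-reading values at the exact surviving index (no local re-search on
  the unsmoothed curve) is the literal reading of the index-re-application
  rule; a local maximum search would report slightly higher peaks on noisy
  curves.
* Acceptance is amplitude-selective under noise: low-amplitude stances
  are rejected more often, so step-pooled means sit a few tenths of a
  percent above the generated population at the steep downhill grades.
  Participant-first pooling largely cancels this.
* The per-grade summaries assume the grade label is exact; treadmill
  calibration error is not modelled.
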