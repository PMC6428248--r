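---
title: "Mapping duration preferences: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping duration preferences: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomapr)
```

## The problem

Some cortical territories — medial premotor cortex (SMA/pre-SMA) most
prominently — contain neural populations tuned to stimulus *duration*,
and those populations appear to be laid out in an orderly progression:
voxels preferring short durations sit anteriorly, voxels preferring long
durations posteriorly. `chronomapr` implements the full analysis chain
needed to find such *chronotopic maps* in event-related BOLD data and to
quantify how orderly they are, together with a synthetic-data generator
that plants known maps so every stage can be validated end to end.

The pipeline has five stages:

1. **Experiment designs** — two paradigms: a jittered pair-comparison
   design (four first-stimulus durations, 0.2/0.4/0.6/1 s, 16 trials per
   169-volume run at a 1.368-s sampling interval) and a cyclic design
   (ten duration pairs per 44-s cycle, standards 0.2–2 s, comparisons
   1.5× the standard, 220 volumes at TR 2 s, ascending or descending
   cycle order).
2. **Voxel labeling** — either a GLM with one offset-locked regressor
   per duration condition and winner-take-all classification of the
   per-condition t-maps, or a one-dimensional Gaussian duration
   population-receptive-field (pRF) model fit per voxel.
3. **Topography metrics** — weighted relative distances (wRD) of each
   duration-selective cluster from a reference border, slopes of wRD
   over duration rank and a signed-rank test on per-subject slopes,
   binned preferred-duration profiles, weighted centroids, and map
   comparison across experiments.
4. **Tuning analysis** — normalized, offset-aligned responses of labeled
   clusters to preferred and non-preferred durations.
5. **QC** — two venous-artifact screens.

## Stimulus timing conventions

Events live on a continuous run clock in seconds; analyses map a time
$t$ to the volume `floor(t / tr)` (0-based). All duration-condition
regressors and stimulus profiles are locked to the *offset* of the first
stimulus of a pair, because the offset is the moment at which the
stimulus duration is knowable; the simulator uses the same convention,
which makes noise-free recovery exact rather than approximate.

Two timing details are under-determined by the published descriptions
and were fixed here once:

* **Jittered paradigm trial envelope.** The inter-stimulus interval
  (4–5.2 s in 0.08-s steps), the 2-s response cue and the run length
  (169 × 1.368 s = 231.2 s) are prescribed; the remaining slack is
  allocated as a 1-s lead-in plus a fixed 4.5-s inter-trial interval,
  chosen so that even the worst-case sequence (all maximal durations and
  intervals) ends before the run does.
* **Cyclic paradigm padding.** One cycle's nominal content — stimuli
  (27.5 s), per-trial 1.37-s vertical intervals (13.7 s) and the 2.03-s
  inter-cycle interval — totals 43.23 s against a stated 44-s / 22-TR
  cycle; the residual 0.77 s is spent as additional vertical-orientation
  time at the cycle tail, preserving the 22-TR grid.

Within each cycle the standard-first/comparison-first order is
randomized 5/5, and consecutive cycles use complementary patterns. The
complementing matters: with an independent draw per cycle, a pair can by
chance be standard-first in every cycle of a run, in which case one of
the 17 unique durations never occurs as a first stimulus and the
stimulus space loses a bin. Counterbalancing across cycle pairs
guarantees all 17 durations (standards ∪ comparisons:
0.2–3 s) appear as S1.

## The GLM stage

Each duration condition contributes a delta regressor at the S1-offset
volume, convolved with the canonical double-gamma HRF (peak 6 s,
undershoot 16 s, 6:1 peak:undershoot, 32-s support, normalized to unit
continuous-time peak). S2 onsets and response-cue onsets get one
regressor each. High-pass filtering is implemented *inside* the model as
per-run discrete-cosine drift columns at the 0.0083-Hz cutoff
(`floor(2 · T · f_c)` columns for a run of T seconds) plus per-run
intercepts, which keeps the degrees-of-freedom accounting explicit.
Runs are concatenated with shared condition columns and run-wise drift
blocks, so each condition's estimate averages over runs.

A practical note on the drift basis: a DCT projection removes a
basis-aligned cosine exactly, but a sinusoidal drift of arbitrary phase
is only attenuated (about 94 % of its amplitude at the worst phase for a
240-s drift in a 440-s run) because a phase-shifted sinusoid has a
slowly decaying cosine expansion. The simulator's default drift period
(240 s) sits inside the high-pass band for this reason.

Winner-take-all labeling assigns each voxel the duration with the
largest contrast t-value when that value exceeds 3.13, with exact ties
broken toward the shorter duration (deterministic and reported). An
optional face-connected cluster-extent filter (default off) replaces the
random-field familywise correction of full-scale analyses, which is out
of scope at desk scale.

## The duration pRF stage

The pRF model treats each voxel's duration selectivity as a Gaussian
over linearly spaced duration with two parameters: preferred duration μ
and spread σ. For every volume, the predicted neural signal is the
overlap between that Gaussian (unit peak; amplitude is absorbed by the
regression) and the presented-duration profile — an indicator matrix
with a 1 at (offset volume, duration bin) for every S1 event — and the
prediction is the HRF convolution of that series.

Fitting is coarse-to-fine:

* **Coarse:** exhaustive grid over μ ∈ {presented durations} and
  σ ∈ {0.05, 0.10, …, 1.0} s, maximizing the R² of the linear fit
  (prediction + intercept). The σ grid's 1-s ceiling encodes the
  empirical observation that credible duration-tuning spreads stay below
  one second; wider fits are a venous red flag (see QC).
* **Fine:** Nelder–Mead refinement (relative tolerance 1e-6) restarted
  from the best grid point of each of the top three distinct-μ
  candidates, with μ clamped to the presented range and σ to the grid
  range. The restarts matter: a voxel whose true preferred duration
  falls *between* presented bins (e.g. 2.8 s between the 2.7-s and 3-s
  bins) can strand a single start on a boundary local optimum at R² ≈
  0.97; with restarts, noise-free recovery is exact to ~1e-4 s. The
  refinement keeps whichever solution scores higher, so it can never
  degrade the grid optimum.

Negative-amplitude solutions are assigned R² = 0 — a tuned response is a
positive deflection, and allowing negative gains would let the model fit
inverted tuning curves. Voxels pass into further analyses only with
R² > 0.1. Labels are the fitted μ snapped to the nearest presented
duration.

## Topography metrics

All lattice geometry uses voxel centers at `(index − 1) × voxel_size`
mm, and *face* adjacency (4 neighbors in a 2-D sheet, 6 in 3-D); the
neighborhood convention and whether a voxel counts itself are exposed as
parameters, with self-exclusion the default.

For a duration label with `Nvd` voxels, each voxel gets weight
`w = Nnbrs / Nvd` (its same-label face-neighbor count over the cluster
size), and

> wRD = Σᵢ wᵢ · RDᵢ / Nvd,  RDᵢ = D1ᵢ / TD,

where `D1` is the distance from the reference (posterior) border along
the map axis and `TD` the border-to-border depth. Clustered voxels thus
count for more than scattered ones, and wRD ∈ [0, 1] is 0 when the
cluster hugs the reference border. A map whose preferred durations
lengthen toward the reference border yields wRD values that *decrease*
with duration; the least-squares slope of wRD over duration rank
(1…k, matching equally spaced plotting; a per-second slope is also
reported) is therefore negative for an orderly map. Slopes can be split
at 1 s into sub- and suprasecond segments. Across subjects, slopes are
tested against zero with an exact one-sample Wilcoxon signed-rank test,
alternative "less" (the published description names a rank-sum test for
what is structurally a one-sample hypothesis; the signed-rank form is
the coherent reading). Zeros are dropped and counted; exact enumeration
is used up to n = 15 when no absolute ties exist.

Preferred-duration profiles bin labeled voxels into 1.5-mm parallel
planes along the map axis; each bin's preferred duration is its majority
label (ties toward the shorter duration), positioned at the bin center's
relative distance from the reference border. Subjects' (distance,
duration) pairs are pooled, sorted, and smoothed by averaging every five
consecutive values. Weighted centroids count each voxel's position as
many times as its same-label neighbor count, falling back (flagged) to
the unweighted mean when every voxel of a label is isolated. Map
comparison reports, per shared label, centroid-to-border distances and
the voxelwise label overlap (identical in both / labeled in either),
plus map extents and per-label cluster-size proportions. Per-subject
slopes can be correlated with behavioral accuracy and with the
coefficient of variation (CV = SD/duration) by Kendall's τ-b.

## Tuning analysis

Cluster responses are normalized as percent signal change against each
voxel's grand-mean baseline across runs (a per-timepoint baseline is
available behind a flag), averaged over the cluster's voxels and then
over runs, and scaled by the trace's own standard deviation — so a
normalized trace has unit SD by construction, and the procedure is
invariant to rescaling the raw signal. Responses are sampled at a single
volume, the second after each S1 offset, and averaged within condition.
Profiles are normalized to the preferred-duration response (exactly 1 at
the PD). For the cyclic paradigm the 17 durations can be collapsed onto
the 10 trial types, durations occurring in two pairs (0.6, 1.2, 1.8 s)
contributing to both with occurrence weights; PD ± k neighborhoods are
defined on the condition rank scale, truncated at the ends. Signed-rank
comparisons of PD vs PD±1 and PD vs PD±2 (or (PD ∪ PD±1) vs PD±2) test
the enhancement-near/suppression-far signature. Cycle-locked waveforms
reshape a trace into 22-volume cycles, time-reverse descending runs, and
average.

## The synthetic generator

`make_truth_chronomap()` plants per-voxel Gaussian tuning (μ*, σ*,
amplitude, baseline) on a lattice with μ* linear along one axis between
the experiment's duration endpoints, optional Gaussian jitter, and a
`shuffled` variant that permutes μ* across voxels (destroying topography
while preserving its distribution). `simulate_bold()` places a tuned
impulse at every S1 offset (height `amplitude · exp(−(d − μ*)²/2σ*²)`),
optionally at S2 offsets with half gain (default on: it stresses the
S1-locked analyses with realistic contamination), convolves with the
same canonical HRF, and adds baseline, a sinusoidal drift and white
noise, all seeded. `simulate_behavior()` draws scalar-timing percepts
(SD proportional to duration; Weber fraction 1/sensitivity) and scores
the comparison, yielding per-condition accuracy and CV for the
slope–behavior correlation.

What the generator does *not* emulate: physiological and temporally
autocorrelated noise, motion, multi-subject anatomical variability,
cortical surfaces and geodesic distances (borders here are planar, and
distances are measured along a lattice axis). Passing tests therefore
demonstrate that the *estimators* are correct and that the pipeline
recovers planted structure under white noise — not that real scans meet
the model's assumptions.

## Validation choices and problem sizes

The test-suite checks run at desk scale, sized so the whole suite stays
in minutes on one core; these are the package's own validation
conditions:

* **Oracle equivalence.** wRD against a brute-force double-loop
  implementation on 50 random 12×12 label maps (agreement to 1e-12);
  GLM t-maps against explicit normal equations on 50 voxels × 200
  volumes (1e-8); signed-rank p-values against full 2ⁿ sign-pattern
  enumeration; Kendall τ against O(n²) pair counting; weighted
  centroids against explicit position repetition.
* **Recovery.** 300 voxels under the 17-duration cyclic design:
  noise-free, median |μ̂ − μ*| ≤ 1e-3 s with all R² > 0.99; with white
  noise calibrated to a mean R² ≈ 0.3 (noise SD = signal SD ×
  √(0.7/0.3)), median |μ̂ − μ*| ≤ 0.2 s. Winner-take-all labeling on a
  noise-free 100-voxel jittered-paradigm simulation recovers ≥ 95 % of
  suprathreshold voxels at the duration nearest their planted μ*.
* **Detection.** 100 cohorts of 10 subjects each, a subject being a
  12×12 lattice with an anterior-short gradient, μ* jittered by 0.2 s
  and snapped to the four-duration label set (standing in for a
  moderate-noise label map; the BOLD→GLM→label path is validated
  separately): the slope test rejects at p < 0.05 in ≥ 95 cohorts, and
  in ≤ 10 when gradients are shuffled.
* **Tuning.** Noise-free cluster profiles are strictly decreasing in
  distance from the preferred duration after averaging conditions at
  tied distances (ties are equal in expectation and ordered only by
  HRF-tail leakage between trials), and exactly 1 at the PD. The tuning
  fixture simulates S1 responses only, since the measured quantity is
  the S1-offset-locked response; S2 contamination is exercised in the
  labeling tests, where the S2 regressor absorbs it.

## Degenerate inputs and numerical conventions

Constant (zero-variance) voxel series are excluded from pRF fits with a
flag rather than fitted; zero baselines and zero-variance traces are
errors in normalization (the contract output is unit SD, which cannot be
met); labels absent from a map, empty masks, and voxels outside the map
borders raise informative errors. Volume indexing guards the
`floor(t/tr)` boundary with a 1e-9 tolerance so offsets landing exactly
on a volume edge are assigned deterministically. Label files encode
durations as integer milliseconds (0 = unlabeled) with a JSON sidecar
mapping codes back to seconds.

## Known limitations

* Borders and distances are planar/axis-aligned; surface flattening and
  geodesic measurement of real cortical maps are out of scope, so wRD
  values here are comparable within the synthetic geometry only.
* The GLM assumes independent homoscedastic errors (no AR modeling or
  nonsphericity correction) — adequate for white-noise simulations,
  optimistic for real scans.
* Group-level inference is limited to the across-subject slope test;
  no random-effects ANOVA or template morphing is provided.
* The behavioral model is a deliberately simple scalar-timing rule,
  sufficient to drive the slope–behavior correlation machinery but not a
  psychophysical model of timing.
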