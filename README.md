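# chronomapr

Topographic duration-preference mapping for event-related fMRI.

Several cortical regions — medial premotor cortex above all — contain
neural populations tuned to stimulus duration, arranged so that
neighboring patches prefer neighboring durations ("chronomaps").
`chronomapr` implements the analysis chain that discovers such maps in
BOLD timeseries and quantifies how orderly they are, plus a synthetic
BOLD generator with planted gradients so the whole chain can be
validated end to end.

**Labeling.** Two routes produce a per-voxel duration-preference label
map:

* a GLM with one delta regressor per duration condition locked to the
  *offset* of the first stimulus, canonical double-gamma HRF,
  discrete-cosine high-pass (0.0083 Hz) inside the model, and
  winner-take-all classification of the per-condition t-maps at
  t > 3.13;
* a 1-D duration population-receptive-field (pRF) model: per voxel a
  Gaussian tuning curve over duration with preferred duration μ and
  spread σ, whose overlap with the presented-duration profile,
  HRF-convolved, is fit to the timecourse by a coarse grid search plus
  Nelder–Mead refinement; voxels enter further analyses when R² > 0.1.

**Topography.** For each duration label with `Nvd` voxels, each voxel
is weighted by its clustering, `w = Nnbrs / Nvd` (face-adjacent
same-label neighbors over cluster size), and the weighted relative
distance from the reference border is

    wRD = Σᵢ wᵢ · RDᵢ / Nvd,   RDᵢ = D1ᵢ / TD

with `D1` the distance from the reference border along the map axis and
`TD` the total border-to-border depth. An orderly map (short durations
far from the posterior border, long durations near it) gives wRD
*decreasing* with duration, i.e. a negative least-squares slope over
duration rank; per-subject slopes are tested against zero with an exact
one-sample Wilcoxon signed-rank test. Preferred-duration profiles
(majority label in 1.5-mm bins), neighbor-weighted centroids, cross-map
comparison (centroid shifts, label overlap, cluster-size proportions)
and Kendall-τ correlations of slopes with behavioral accuracy/CV
complete the picture. Duration-tuning analysis and venous-artifact QC
round out the pipeline.

## Worked example

Simulate one subject with a planted anterior-short gradient (12×12
lattice, four runs of the jittered pair-comparison paradigm, white noise
SD 0.2), label voxels by GLM winner-take-all, and quantify the map:

```r
library(chronomapr)

cfg <- default_config("exp1")
cfg$design$n_runs <- 4L
cfg$truth$shape  <- c(12, 12, 1)
cfg$noise$white_sd <- 0.2
cfg$seed <- 7L

res <- run_pipeline(cfg)
res$wrd
#>   duration         wrd nvd mean_weight
#> 1      0.2 0.112689394  24  0.11805556
#> 2      0.4 0.061425061  37  0.08473338
#> 3      0.6 0.028613164  46  0.06994329
#> 4      1.0 0.007902251  37  0.08473338
res$slopes$slope
#> [1] -0.03472108
res$report$n_labeled
#> [1] 144
```

All 144 voxels exceed the t > 3.13 labeling threshold, and wRD falls
monotonically from the 0.2-s cluster (farthest from the posterior
border) to the 1-s cluster (on it): the planted anterior-short gradient
comes back as a negative wRD slope (−0.035 per duration rank). With ten
such subjects, `test_slopes()` gives the exact signed-rank p-value for
the cohort (all-negative slopes at n = 10 → p = 2⁻¹⁰ ≈ 0.00098).

The pRF route works the same way on the cyclic paradigm:

```r
asc <- build_exp2_design("ascending", n_cycles = 10, seed = 3)
tm  <- make_truth_chronomap(c(15, 20, 1), c(0.2, 3), sigma_star = 0.3,
                            seed = 204)
bold <- simulate_bold(tm, asc$events, asc$scan, noise_spec(), s2_gain = 0)
pm <- prf_map(bold, events = asc$events, scan = asc$scan)
median(abs(pm$fits$mu - as.vector(tm$mu_star)))
#> [1] 0
min(pm$fits$r2)
#> [1] 0.9999997
```

A thin command-line wrapper over the same pipeline lives at
`inst/cli/chronomap.R`
(`Rscript chronomap.R simulate --config cfg.yaml --out dir`).

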