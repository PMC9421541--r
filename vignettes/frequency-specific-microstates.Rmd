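---
title: "Frequency-specific EEG microstate analysis with microspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-specific EEG microstate analysis with microspect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microspect)
```

## The model

Resting-state EEG is not a stationary mixture: the scalp field organizes
into brief (roughly 50–120 ms) epochs during which the *topography* — the
spatial pattern of voltages across electrodes — stays quasi-stable while its
polarity may invert. These epochs are EEG microstates. A small set of
prototype maps (canonically labeled A–E: two mirror-image diagonal
gradients, an anterior–posterior gradient, a fronto-central maximum, and a
centro-posterior maximum) explains most of the topographic variance of the
recording.

`microspect` implements the full analysis chain for comparing microstate
dynamics between two groups, both on broadband (1–30 Hz) signals and within
canonical frequency bands (delta 1–4, theta 4–8, alpha 8–12, beta 15–30 Hz):

1. **Segmentation (fitting).** Topographies at global field power (GFP)
   peaks — moments of maximal spatial signal-to-noise — are clustered with a
   polarity-invariant ("modified") k-means: similarity is the absolute
   spatial (Pearson) correlation across channels, and each cluster's
   prototype is the dominant eigenvector of the outer-product sum of its
   assigned topographies, so a map and its negative are the same state. The
   best of `n_repetitions` random restarts is kept, scored by global
   explained variance,
   GEV = Σᵢ GFPᵢ² rᵢ² / Σᵢ GFPᵢ², where rᵢ is the correlation between peak
   *i* and its assigned map.
2. **Aggregation.** Subject-level map sets are aligned (optimal one-to-one
   pairing maximizing mean |r|, exhaustively over all k! permutations, with
   polarity matched per map) and averaged into group maps; group maps are
   checked for topographic equivalence (matched |r| ≥ 0.95) and averaged
   into grand-mean maps, relabeled by best match to the canonical A–E
   templates.
3. **Backfitting.** Every sample of the (band-filtered, average-referenced)
   recording is assigned to the grand-mean map with the highest |r|;
   samples below r = 0.50 stay unassigned. Labels are then smoothed (window
   ±7 samples, factor 10) and runs shorter than 3 samples are split between
   their neighbors. Per map and band, three temporal measures follow from
   the run-length encoding: occurrence (runs/s), mean duration (ms), and
   time coverage (fraction of samples).
4. **Group statistics.** Each of the 75 cells (3 measures × 5 bands × 5
   maps) is tested with a two-sided permutation test on the group-mean
   difference (10,000 label shuffles, add-one p-value estimator), Bonferroni
   corrected over the 75 tests, with Cohen's d (pooled SD, group 1 − group 2)
   as the effect size.
5. **Classification.** Frequency-specific models (3 measures × 5 maps within
   one band = 15 features) and map-specific models (3 measures × 5 bands
   within one map = 15 features) are ranked by ReliefF (15 nearest
   neighbors) and classified with a linear SVM under 10-times-repeated
   stratified 10-fold cross-validation, reporting accuracy, sensitivity,
   specificity and AUC per feature count k = 1…15. Models sharing a CV seed
   have paired folds and can be compared with a sign-flip permutation test
   on fold-wise AUC differences.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_gfp_peaks` | 1000 | GFP peaks per subject submitted to clustering (random subset if more exist) |
| `n_repetitions` | 100 | k-means restarts; GEV of the kept solution is non-decreasing in this |
| `k_range` | 4–7 | candidate map counts; k selected by split-level reliability (mean subject-to-group absolute map correlation), ties to the smaller k |
| assignment threshold | 0.50 | minimum absolute correlation for a sample to receive a label |
| smoothing window | ±7 samples | neighborhood whose label counts enter the smoothing score |
| smoothing factor | 10 | weight of the neighborhood count, as factor/(2·window) per neighbor; 0 disables smoothing exactly |
| minimum duration | 3 samples | shorter runs are split between their neighbors, iteratively |
| permutations | 10,000 (group tests), 1000 (clinical correlation) | label shuffles per test |
| SVM cost | 1 | linear SVM regularization constant |
| ReliefF neighbors | 15 | nearest hits/misses per instance |

The smoothing score for map *m* at sample *t* is
`|r|(t, m) + factor/(2·window) · #{labeled m within ±window}`, iterated to a
fixed point (at most 50 sweeps). Unassigned samples can gain a label only if
their adjusted score reaches the assignment threshold. Because the factor
enters per neighboring sample, `factor = 0` reduces the smoothing to the
identity — a property the tests pin down.

A note on units: at 250 Hz the ±7-sample window spans 56 ms and 3 samples
are 12 ms. Both are expressed in samples and exposed as arguments, so other
sampling rates simply rescale.

## The synthetic cohort generator

No public recording accompanies the group analysis this package targets, so
validation runs end-to-end on simulated cohorts with known ground truth.
`simulate_subject()` draws:

- a **semi-Markov state sequence**: states (one per template map) persist
  for gamma-distributed dwell times (shape 2, mean 80 ms) and never
  self-transition. The gamma law keeps dwell times positive and
  non-memoryless; its mean and shape are configurable because no generative
  law for microstate durations is established.
- a **polarity-flipping, band-limited carrier**: while a state is active,
  its template is modulated by band-passed white noise (default: alpha,
  8–12 Hz, for every map) with a random sign per segment, since microstates
  are defined up to polarity.
- **between-subject heterogeneity**: each subject's mean dwell time, per-map
  carrier amplitude, and signal-to-noise ratio are lognormal around the
  configured values (CV 0.3 each). Real cohorts vary widely in band power
  and microstate stability; without this heterogeneity a planted group
  difference separates the groups perfectly and every classifier saturates,
  which matches no clinical dataset.
- **structured noise**: spatially mixed, temporally pink (AR(1), coefficient
  0.95) Gaussian noise, scaled to the configured SNR. Uncorrelated white
  sensor noise would be unrealistically easy to cluster, and resting EEG
  background is dominated by low frequencies.

A group-2 deficit is planted on map E only, as a multiplicative scale on its
dwell-time mean and/or its transition probability, mirroring reduced
duration and occurrence of a single map.

**Band-specific dynamics.** With a single state process, every frequency
band carries *identical* dynamics by construction, and band-pass filtering
can only remove information — the broadband analysis is then always the
best-measuring one. Real EEG superposes generators with different spectral
signatures and different dynamics, which is exactly why spectral
decomposition of microstates can add information. The generator models this
with an optional background process (`distractor_weight`, default 0): an
independent semi-Markov sequence over the same templates, carried by 1–8 Hz
oscillations and free of any group effect, superposed at a configurable RMS
ratio. With it enabled (weight 1), broadband measures reflect a mixture of
the two processes, so a deficit planted on the alpha-band process is
*diluted* in broadband and isolated by alpha-band filtering — and the
alpha-band model outperforms the broadband model, the directional pattern
the group-comparison experiments probe. The ground truth always refers to
the primary (alpha) process, which is why the background process defaults
off for parameter-recovery checks.

What the generator does **not** emulate: dipolar forward physics and volume
conduction, eye/muscle artifacts, line noise, non-stationary vigilance
drifts, or band-specific topography differences. Passing tests therefore
show that the *pipeline* recovers planted dynamics and effects under
realistic noise and heterogeneity — not that it is robust to every artifact
of real recordings.

## Numerical and design choices

- **GFP** is the population (divide-by-n) standard deviation across
  channels, equal to the RMS of the average-referenced sample — the
  convention in the microstate literature.
- **Filtering** is a 4th-order Butterworth applied forward and backward
  (zero phase), so topography timing is not shifted; band edges at or above
  Nyquist are errors.
- **k-means details**: assignment ties break to the lowest map index; an
  empty cluster is re-seeded from the worst-fit observation; convergence is
  a relative GEV change below 1e-6 or 300 iterations; clustering is
  invariant to global sign flips and positive rescaling of the data.
- **Alignment** maximizes mean |r| over all k! pairings (k ≤ 7, so
  exhaustive search is exact and cheap); per-map polarity is chosen to make
  the signed matched correlation positive. Reliability-based k selection
  breaks ties toward the smaller k.
- **Boundary censoring**: a label run touching the recording edge or an
  epoch-concatenation seam has censored true length; it counts toward
  occurrence and coverage but not mean duration. Unassigned samples break
  runs.
- **Minimum-duration rule**: a short run is split at its midpoint, the left
  half relabeled to the left neighbor and the right half to the right
  neighbor (a run at the sequence edge is absorbed entirely into its single
  neighbor), applied iteratively until no short run remains.
- **Permutation p-values** use the add-one estimator
  (1 + #extreme)/(n_perm + 1), never zero; per-cell seeds are derived
  deterministically from the family seed and the cell identity, so results
  do not depend on table row order. The test statistic is the raw mean
  difference; zero pooled variance yields p = 1 by convention.
- **Leakage control**: within every CV fold, feature standardization and
  ReliefF ranking are fitted on the training folds only (a
  whole-data-ranking mode exists behind `leakage_safe = FALSE` for
  comparison with analyses that rank once before CV). A canary test plants
  a label-copy feature into test folds only and verifies accuracy stays at
  chance.
- **Positive class** for sensitivity/specificity and AUC orientation is the
  patient group (group 2). Cohen's d is reported as group 1 − group 2, so a
  patient deficit appears as *positive* d in the table; outputs that mirror
  the patient-minus-control convention negate it explicitly.
- **Ground-truth recovery** is validated against the raw assignment
  (smoothing disabled): temporal smoothing and the minimum-duration rule
  are regularizers for noisy data that, by construction, erase true
  segments shorter than their scales (with the default window, converged
  smoothing relabels 4–5% of noise-free samples around short true
  segments). Their behavior is pinned by dedicated tests instead of by the
  recovery comparison.

## Problem sizes used by the test suite and acceptance script

Simulated recordings are 10–60 s (full cohorts: 40–45 s per subject) at
250 Hz with 19 channels; cohorts range from 4/group (smoke and recovery
checks) through 30/group (detection power, 5 replicate cohorts) to 61/group
(the classification experiment). Clustering restarts are reduced to 10–20
for cohort-level runs. These sizes were chosen so that every validated
property is comfortably away from its sampling noise floor while the whole
suite stays quick; the statistical conclusions do not depend on them.

## A worked example

```{r example, eval = FALSE}
library(microspect)

cfg <- synthetic_config(duration = 45, snr = 5, n_per_group = 30,
                        group2_mapE_duration_scale = 0.6,
                        distractor_weight = 1, seed = 1)
cohort <- simulate_cohort(cfg)
res <- run_full(cohort, k = 5,
                cluster = cluster_config(n_repetitions = 20),
                family = test_family(n_permutations = 10000),
                seed = 1)

res$equivalence$pass          # group map sets topographically equivalent?
head(res$stats)               # strongest cells first (map E duration/coverage)

alpha <- evaluate_model(
  assemble_features(res$measures, "frequency_specific", "alpha"), seed = 2)
broad <- evaluate_model(
  assemble_features(res$measures, "frequency_specific", "broadband"), seed = 2)
rbind(alpha = alpha$metrics[1, ], broadband = broad$metrics[1, ])
compare_models(alpha, broad, at_k = 1)
```

## Known limitations

- The smoothing arithmetic follows the classical window-count-penalty
  formulation; plug-in implementations in other toolboxes differ in detail,
  so absolute duration values are comparable only within one pipeline.
- Band-specific analyses backfit the *shared broadband* grand-mean maps to
  band-filtered signals (keeping features comparable across bands) rather
  than re-clustering per band; narrowband filtering lengthens apparent
  durations through its impulse response, so band measures are
  within-pipeline quantities, not physiological constants.
- The alignment's "minimize dissimilarity" reading of map ordering is one
  of two possible interpretations of the underlying convention; the
  opposite direction can be obtained by negating the objective, but the
  matched-similarity reading is the only one under which group averaging is
  meaningful.
- Effect sizes and accuracies obtained on synthetic cohorts characterize
  the pipeline under the generator's assumptions; they are not predictions
  of clinical performance.
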