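---
title: "Detecting freezing of gait from three wearable inertial sensors"
author: "fogkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from three wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogkit)
```

## The problem

Freezing of gait (FOG) is an episodic inability to produce effective
stepping that affects many people with advanced Parkinson's disease. It
comes in two signal phenotypes: *trembling* freezing, where the legs
oscillate at 3–8 Hz without forward progression, and *akinetic* freezing,
a near-total movement arrest. Clinical quantification relies on
video-annotated FOG-provoking tests, which is slow and rater-dependent.
`fogkit` implements an automated, patient-independent detection pipeline
from three body-worn inertial sensors — one on the lower back and one
above each ankle, each recording tri-axial acceleration (m/s², axes
vertical V, anterior–posterior AP, medio-lateral ML) and angular velocity
(deg/s) at 128 Hz — together with a synthetic cohort generator so that
every stage is testable without clinical data.

## The pipeline

1. **Filtering.** Every axis is low-pass filtered with a second-order
   Butterworth at 15 Hz. The filter is applied forward–backward
   (zero-phase, with odd-reflection padding to suppress startup
   transients), so the effective attenuation is the squared magnitude
   response, $|H(f)|^2 = 1/(1+(f/15)^4)$, and episode boundaries are not
   shifted by filter delay.
2. **Annotation cleaning.** Ground-truth FOG intervals closer than 1 s are
   merged, then surviving episodes shorter than 1 s are dropped (merge
   first, so fragmented annotations of one real episode survive). The
   operation is idempotent.
3. **Windowing.** Trials are cut into 3 s windows. A window is a FOG
   example when it overlaps the cleaned annotations by at least 1.5 s.
   Training windows use asymmetric steps — 0.6 s (80% overlap) for FOG
   windows and 1.5 s (50% overlap) for non-FOG windows — which oversamples
   the rarer FOG class; test windows lie on the uniform 1.5 s grid. Both
   grids are anchored at trial start, and windows extending past the trial
   end are discarded (every spectral feature needs 3 s of real signal).
4. **Features.** 86 features per window (see below), including the
   *freezing index* — the ratio of integrated power spectral density in
   the freeze band (3–8 Hz) to the walk band (0.5–3 Hz) of the AP leg
   acceleration, taken per leg and maximized over legs — and two
   trunk–leg RMS ratio features motivated by the observation that during
   freezing the trunk's movement drops while the legs still move.
5. **Selection.** Per training fold: Welch t-tests with Bonferroni
   correction (always dividing by the full manifest size 86), greedy
   minimum-redundancy maximum-relevance (MRMR, MID scheme with
   equal-frequency 10-bin mutual information) ranking of the survivors,
   then the feature count $k$ minimizing mean misclassification error on
   inner subject-wise 5-fold splits (ties to the smallest $k$).
6. **Classification.** An SVM with RBF kernel on z-scored features
   (standardization parameters from the training windows only). Validation
   is leave-one-patient-out (LOPO): each subject's windows are scored by a
   model that never saw that subject. A final model ranks features by
   their *commonness* across the LOPO folds (ties by mean MRMR rank, then
   lexicographically), picks $k$ by training-cohort inner-fold error, and
   is evaluated on held-out test subjects.
7. **Episodes and outcomes.** Overlapping test-window predictions are
   fused by a per-sample strict-majority vote, converted to intervals, and
   cleaned with the same rules as the annotations, making predicted and
   true episodes directly comparable. Derived outcomes are percent time
   frozen, total frozen time and episode count. Window metrics are
   sensitivity, specificity and accuracy (a signal with no FOG windows
   scores 100% sensitivity by convention), plus ROC/AUC from the SVM's
   signed decision scores; fold ROCs are averaged vertically on a fixed
   specificity grid, and the optimal operating point is the curve point
   nearest (0, 1).

## The 86-feature manifest

The full appendix-level listing of the original feature set is not
available, so the package fixes a canonical 86-entry manifest spanning
every named family, with the documented 14-feature final-model set as an
exact subset:

* per channel group (back accelerometer, back gyroscope, leg
  accelerometers, leg gyroscopes) and axis (V, AP, ML): mean, SD,
  skewness and range of cumulative sum (48);
* tri-axial RMS per group (4);
* per group: freezing index, band power, peak frequency and spectral
  entropy in the walk and freeze bands on designated axes (28);
* inter-leg correlation and inter-leg mean-magnitude min/max ratio of the
  gyroscope ML axis (2);
* walk-band spectral skewness of back-accelerometer AP and back-gyroscope
  ML (2);
* the two trunk–leg ratios: maximum leg gyroscope tri-axial RMS over back
  accelerometer RMS, and over back gyroscope RMS (2).

Leg-sourced features aggregate over legs with the maximum, except the
range-of-cumulative-sum features of leg-accelerometer V and leg-gyroscope
ML, which use the minimum (as in the final-model set); swapping the leg
sensors therefore never changes a value. Degenerate inputs follow fixed
conventions: 0/0 ratios are 0, correlations with a zero-variance input are
0, the entropy and skewness of a zero-power band are 0, and the peak
frequency of a zero-power band is the band's lower edge. The comparator
feature set from the back sensor (axis-mean differences, per-axis moments,
inter-axis correlations, band SDs/skewnesses of the summed-axis spectrum,
harmonic peaks, spectral center of mass, and the first three principal
components of the 0.04–8 Hz spectrum, basis fit on training windows only)
is provided for method comparison; the summed-axis signal is the sample-wise
sum V+AP+ML.

## Spectral estimation choices

Windows are 384 samples, too short for multi-segment averaging, so the
package uses a single-segment Hann-tapered periodogram normalized to be
Parseval-consistent, and integrates bands by the trapezoid rule over the
discrete grid with inclusive edges. A unit sinusoid on a DFT bin spreads
its power 1:4:1 over three bins, which the tests use as the analytic
oracle for band powers; a band edge adjacent to a peak loses the
endpoint's half-weight under the trapezoid rule, which is part of the
estimator's definition, not an error.

## The synthetic cohort generator

The generator emulates the spectral structure that makes FOG detectable,
not biomechanics:

* **walking** — a per-subject cadence sinusoid (default 1.8 Hz, jittered
  per subject within the 0.5–3 Hz walk band) plus a first harmonic at 40%
  amplitude, legs in antiphase, trunk at comparable amplitude;
* **trembling FOG** — a per-subject tremor oscillation (4–7 Hz, inside
  the 3–8 Hz freeze band) on the legs with the trunk attenuated by a
  dissociation factor of 0.05, the mechanism behind the ratio features;
* **akinetic FOG** and **quiet standing** — noise-only movement. These two
  are deliberately indistinguishable from the signals alone: akinetic
  windows are FOG in the ground truth and standing windows are not, which
  bounds achievable accuracy and is the main error source in every result
  below;
* gravity as a constant 9.81 m/s² offset on each vertical accelerometer
  axis, white sensor noise everywhere (0.05 m/s², 1 deg/s), and 0.2 s
  raised-cosine cross-fades at state changes.

Episodes are scheduled to a target fraction of time frozen (default 25%,
scaled by trial difficulty) with log-normal durations and at least 1.2 s
of duration and inter-episode gap, so generated ground truth is stable
under annotation cleaning; a `dirty` mode relaxes the minima to exercise
the cleaner. Because the generator's walking and tremor are narrowband,
passing tests show that the pipeline recovers planted spectral structure
under realistic noise and subject heterogeneity — not that it would reach
the same numbers on clinical recordings, whose gait harmonics, artifacts
and annotation uncertainty are far richer.

## Design decisions on open points

* **Units and gravity**: accelerometers are fixed to m/s² and gyroscopes
  to deg/s in the file dialect, and gravity is retained (features must
  tolerate the V-axis offset; spectral bands exclude DC).
* **Window grids** are anchored at trial start; when a start lands on both
  training grids the label comes solely from the 1.5 s overlap rule and
  the start is kept once.
* **Episode fusion tie rule**: with the 1.5 s test step, interior samples
  are covered by exactly two windows, so the tie case dominates fusion. A
  strict majority is required: an isolated FOG window outvoted by its two
  overlapping neighbours produces no episode. The alternative (ties vote
  FOG) turns every isolated false-positive window into a 3 s episode,
  which measurably corrupts trial-level percent-time-frozen recovery.
* **Feature-count search cap**: the error curves plateau well before the
  full ranking length, so experiments cap the search at `kMax = 30` by
  default; the search itself remains exhaustive below the cap.
* **Inner evaluation** for the count choice uses subject-wise 5-fold
  splits within the training data (never the held-out LOPO subject), to
  avoid test leakage.
* **SVM hyperparameters**: cost 1 and the 1/(d·variance) gamma heuristic;
  an inner-fold grid search is available but off by default. Class
  imbalance is handled solely by the asymmetric window overlap.
* **Method comparison** (full pipeline vs freezing-index threshold at 2.5
  vs the back-sensor comparator set) is evaluated on the training cohort,
  the larger set, with every method patient-independent over the same
  windows: the pipeline by its LOPO folds, the comparator SVM by LOPO
  with the PCA basis refit per fold, the threshold detector directly.
  Differences are tested with exact two-sided Wilcoxon signed-rank tests
  on per-subject metrics.
* **Experiment sizes**: the packaged experiment simulates 25 subjects with
  two 60 s trials each and holds out 5 subjects (20%) by subject-level
  split. Two trials of 60 s per subject keep single hard akinetic episodes
  small relative to a trial and give 10 held-out trials for the rank
  correlation between predicted and annotated percent time frozen;
  markedly shorter trials make that outcome quantization-dominated.

## Worked example

```{r example, eval = FALSE}
library(fogkit)

cfg <- experimentConfig(sim = simConfig(nSubjects = 10, durationS = 60),
                        seed = 1)
report <- runExperiment(cfg)

report$lopo$mean_metrics   # LOPO sensitivity/specificity/accuracy +/- SD
report$final$chosen_ids    # features of the final model
report$test$metrics        # held-out window metrics and AUC
report$test$outcomes       # per-trial percent time frozen, predicted vs true
report$comparison$table    # proposed vs freezing index vs comparator set
```

## Known limitations

* Akinetic freezing and quiet standing are identical at the signal level
  (by design); their confusion bounds window specificity and adds noise to
  derived outcomes. Real systems disambiguate with context the package
  deliberately ignores.
* The 86-entry manifest is a reconstruction of the feature families named
  in the source material; an authoritative appendix listing would
  supersede it.
* The simulator is narrowband and stationary within states; it does not
  model turning, doorway approaches, festination, or device artifacts.
* Magnetometer channels are ignored, and non-128 Hz recordings are
  rejected rather than resampled.
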