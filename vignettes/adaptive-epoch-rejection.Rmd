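---
title: "Adaptive, acceptance-rate-controlled epoch rejection for block-design fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive, acceptance-rate-controlled epoch rejection for block-design fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsreject)
```

## The problem

Block-design fNIRS measures cerebral hemoglobin changes (ΔO2Hb, ΔHHb,
ΔHb-total, in mM·mm at 10 Hz) across repeated rest–instruction–stimulus
cycles; each cycle contributes one *epoch*, and the activation estimate is
the epoch average. Motion artifacts — common in pediatric cohorts — and
physiological oscillations corrupt individual epochs. Discarding every
suspicious epoch protects against bias but shrinks the sample and inflates
the false-negative rate of the activation test; keeping everything does the
opposite. This package implements a rejection algorithm that makes that
trade-off explicit: an **acceptance rate** — a minimum number of surviving
epochs — bounds how much any noise criterion may reject, and a noise-level
ranking decides *which* flagged epochs go when not all of them can.

## The three noise criteria

Epochs span 13 s prestimulus (10 s baseline + 3 s instruction), the
stimulus (24 s by default) and 13 s poststimulus, on a fixed 0.1-s grid.

1. **Sudden amplitude change with recovery failure**
   (`criterion1_config()`). Consecutive-sample changes above a threshold
   (`jump_threshold`, mM·mm; search range 0.01–0.05, the published
   real-data optimum is 0.047) mark an event; over-threshold runs separated
   by fewer than two quiet samples merge into one event, since a
   multi-sample artifact is one artifact. The signal's base level is
   averaged over 1 s before the event onset and after its end; only a base
   shift above `recovery_threshold` (0.2 mM·mm) — a failure to recover —
   counts as noise. A brief spike that returns to its base level is left
   alone. Severity: the largest base shift.
2. **Excessive prestimulus baseline slope** (`criterion2_config()`). The
   least-squares slope over the full 13-s prestimulus; absolute slopes
   above `slope_threshold` (mM·mm/s; range 0.01–0.05, published optimum
   0.029) flag the epoch. Only the prestimulus is examined: scoring the
   stimulus interval would smuggle in assumptions about the hemodynamic
   response shape. The absolute value is used — the criterion targets
   "extremely high or low" slopes of either sign. Severity: |slope|.
3. **Low inter-epoch correlation sum** (`criterion3_config()`). Each
   retained epoch's Pearson correlations with the other retained epochs
   are summed; epochs falling strictly below the one-sided fence
   `Q1 − k·IQR` (k range 0–3, published optimum 0.6) are outliers.
   Quartiles interpolate linearly between order statistics
   (`quantile(type = 7)`); the fence hangs from Q1, boxplot-style, and is
   one-sided because only *low* similarity indicates noise. Zero-variance
   (flat-lined) epochs are assigned correlation 0 with every partner so
   they remain flaggable. Unlike criteria 1–2, this criterion adapts to
   the individual data set; it is re-evaluated on the survivors at its
   stage, so the fence tracks the current epoch pool. Severity: fence
   minus sum.

## The rejection engine

`apply_rejection()` runs the criteria in order (1 → 2 → 3 by default)
under the policy's acceptance rate:

1. Detect flags among the currently retained epochs.
2. Count what would remain if every newly flagged epoch were rejected.
3. If that count still meets the acceptance rate, reject them all;
   otherwise reject **none** and record the flags (all-or-none per stage).
4. Pass the survivors to the next criterion.
5. After the last stage, each surviving epoch's **noise level** is its
   number of recorded (unacted-on) flags. While survivors exceed the floor
   and a flagged survivor exists, the highest-noise-level epoch is
   rejected; ties break by the larger sum of within-criterion severity
   ranks, then by the lower epoch index. Severities are not recomputed
   during this trim — the ranking is a single pass over the recorded
   flags, not an iterative re-detection.

With `acceptance_rate = "unlimited"` the engine reproduces conventional
rejection: every flag acts immediately and the ranking never fires. The
floor invariant — at least `acceptance_rate` epochs survive, always — is
asserted inside the engine on every run.

Both tie-break rules are design choices (the ordering of equally noisy
epochs is otherwise undefined); they are deterministic and data-driven, so
identical inputs always give identical results. Rejection runs per
channel; `propagate_rejection()` copies a decision made on ΔO2Hb — whose
task response is the most pronounced — to the other signal types of the
session.

## Preprocessing

`preprocess()` applies a first-degree polynomial detrend and a 0.01–0.8 Hz
band-pass (drift and heartbeat removal), then `extract_epochs()` cuts
half-open windows `[onset − 13 s, onset + 37 s)` snapped to the grid and
`normalize_baseline()` zeroes each epoch's first 10 s. The pipeline order
is fixed: detrend → filter → epoch → reject → normalize → activation.
The activation value of an epoch is its mean from 4 s after stimulus
onset to stimulus end; SNR is `20·log10(μ_activation / σ_baseline)` dB,
reported as undefined (`NA`) when the activation mean is non-positive.

Two numerical choices deserve note. First, the band-pass is realized as
cascaded second-order sections (Butterworth Q values) for the high-pass
edge plus a Butterworth low-pass, applied forward–backward: a direct
transfer-function realization of a 4th-order band-pass with a normalized
low edge of 0.002 is numerically degenerate, and zero-phase filtering
avoids epoch-relative latency shifts (whether the original analyses
filtered causally is unknowable; the choice is configurable via
`preprocess_config(zero_phase = )`). Second, filtering pads with
*even* reflection after subtracting the first sample: point-symmetric
(odd) padding anchors hundreds of padded seconds on a single noisy
endpoint sample, injecting that sample's noise into the high-pass trend
estimate for the first epoch; even reflection avoids the injection, and
slow trends are gone before the filter because the detrend runs first.

## The synthetic generator

`generate_recording()` builds `f(t) = h*b + p + m (+ artifacts)`:

* **Task response** `h*b`: a gamma HRF (τ = 1.08 s, n = 3, peak at
  2.16 s) convolved with the session boxcar. The kernel is normalized to
  unit area so each trial's plateau equals its drawn amplitude — that
  makes the boxcar mean and SD directly the activation scale used by the
  SNR calibration and the power study. The session lays out six trials
  with 26-s rests and 24-s stimuli (from the protocol's stated ranges;
  this makes the 50-s trial spacing exactly the epoch length, so windows
  tile without overlap).
* **Amplitude variability**: one Gaussian draw per *recording* by default
  (`boxcar_params(amp_per = )`), representing between-subject response
  variance; the mean/SD ratios studied (0.85, 1, 2) are the average and
  maximum ratios observed across real activation data. Per-trial draws are
  available, but they cannot reproduce the published power results: a
  one-sample t-test on n = 3 epochs with within-signal effect size 2 has
  a power ceiling of 0.71, whereas the reported behavior (80 % power with
  three epochs at ratio 2, and with five at ratio 0.85) matches the
  between-recording model, whose asymptotic power is Φ(ratio) = 0.98 and
  0.80.
* **Physiological noise** `p`: zero-mean Gaussian, SD 1/6, band-passed
  0.08–0.15 Hz with a 4th-order Butterworth response (spontaneous
  low-frequency/Mayer-wave oscillations). Heartbeat and slower waves are
  deliberately not modeled.
* **Machine noise** `m`: white Gaussian with σ set so the
  activation-to-baseline SNR equals the requested value
  (σ = μ/10^(SNR/20)); for null simulations (μ = 0) the reference
  amplitude is supplied explicitly.
* **Artifacts** (optional): each injected event occupies its own randomly
  chosen trial (1 to 6 events, count uniform; an explicit count can be
  forced). An event is a baseline shift with probability 1/2, otherwise a
  spike, recovered or non-recovery with equal probability — the source
  protocol says only "randomized", so these probabilities are exposed
  configuration-free choices. Spikes convolve a 1-s rebound step (width
  unstated in the protocol; 1 s chosen) with the HRF derivative — or its
  non-recovery variant, which keeps h′ to its maximum and continues as
  2h′ − max h′, settling at −max h′ so the signal never returns — scaled
  to a peak drawn from 0.14–0.48 with random sign, placed at least 2 s
  from the window edges so base-level windows stay measurable. Baseline
  shifts add a slope (mean 0.025 mM·mm/s, SD defaulting to 0.0125, the
  midpoint of the stated 0–0.025 range, random sign) supported on the
  prestimulus interval only: the epoch's baseline drifts away from its
  surroundings, which is exactly what criterion 2 measures. Every event
  is returned in a ground-truth annotation.

What the generator does *not* emulate: serially correlated physiological
structure beyond the stated band, channel covariance, probe-geometry
effects, task-correlated motion, and HHb dynamics distinct from O2Hb.
Passing tests on this generator therefore demonstrate the algorithm's
mechanics and its behavior under the stated noise models — not
performance on any particular real data set.

## Power study and false-negative rates

`power_simulation()` reproduces the random-rejection experiment: generate,
preprocess, epoch, drop k epochs at random, t-test the remaining
activation values against zero (one-tailed, α = 0.05 by default — the
protocol does not state the simulation test's tail or level, so the
conventional choice is used and configurable; the real-data reproducibility
targets use one-tailed α = 0.025). Simulations are paired across grid
cells by deriving each simulation's seed from the cell-independent index,
so power *differences* (e.g. the plateau comparison) are far more precise
than the marginal binomial error. Typical behavior: power collapses to
the significance level near −40 dB, rises steeply through −10 dB, and
plateaus above about −5 dB; higher mean/SD ratios buy adequate power
(≥ 80 %) with fewer epochs.

`fnr_experiment()` injects artifacts, optimizes the criterion thresholds
on a grid for the lowest false-negative rate under the
acceptance-controlled engine (floor 3), and compares against no
rejection; `hrf_recovery_score()` compares the retained-epoch average
against the known true response. The experiments run at 10 dB — mid-
plateau, the "moderate-to-high SNR" regime where artifacts, not machine
noise, limit detection. At strongly negative SNR, machine noise dominates
the inter-epoch correlations, criterion 3 flags indiscriminately, and no
rejection scheme helps — consistent with the flat low-SNR power floor.

## Threshold optimization

`grid_search()` spans acceptance rates (3, 4, unlimited), criteria
subsets in the fixed order 1 → 2 → 3, and per-criterion threshold grids.
The full published search grids (0.01–0.05 step 0.001 for criteria 1–2;
0–3 step 0.1 for criterion 3) are available but default to a five-fold
coarser step so a full search stays desk-scale. *Independent* mode scores
every cell on every cohort; *sequential* mode keeps only training-optimal
cells and re-scores them on validation cohorts — its survivors are by
construction a subset of the training-optimal independent cells.
Reproducibility targets (`stat_target()`) encode expected group-level
inferences: plain group activation, the pre-administration mean of the
pre-medication and pre-placebo conditions, or the inter-medication
difference-of-differences `(post−pre medication) − (post−pre placebo)`,
each tested per subject with a one-tailed one-sample t-test at α = 0.025.
Activation is pooled over the subject's region-of-interest channels
before testing (channel-wise testing remains possible by treating
channels as subjects). `rejection_accuracy()` scores agreement with
reference (e.g. visually assigned) labels as (TP + TN)/total.

## Problem sizes and runtime choices

The test suite and the acceptance script use 1000 simulations per power
cell, 200-signal batches for the false-negative-rate and recovery
experiments, and the complete 2^18-pattern enumeration of the engine
against a literal five-step simulator; these sizes keep every quantity's
binomial error a few percent while a full run completes in minutes on one
CPU. Cohort examples use 10 subjects per group at 5–10 dB.

## Known limitations

* The criteria assume a constant-interval block design; criterion 3 is
  unsuitable for imbalanced paradigms or resting-state data.
* Criterion thresholds are sampling-rate- and instrument-dependent;
  re-tuning is expected for data not resembling the defaults.
* The acceptance floor is enforced per channel; a session-level floor
  across a region of interest is not implemented.
* Visual-rejection reference labels can be scored against, but the
  package does not attempt to reproduce any particular study's real-data
  accuracies, which depend on non-public recordings.
* No artifact *correction* (spline, wavelet, PCA/ICA) is provided —
  rejection with a floor is the point: corrected data risk waveform
  distortion that is hard to audit in clinical cohorts.
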