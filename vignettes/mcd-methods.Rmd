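---
title: "Modelling audiovisual causality and temporal-order judgments with the multisensory correlation detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling audiovisual causality and temporal-order judgments with the multisensory correlation detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdmeg)
```

## The model

When a click and a flash occur close together in time, observers tend to
attribute them to a common cause and can judge which modality led.  The
multisensory correlation detector (MCD) explains both judgments with a
single Hassenstein–Reichardt-style circuit.  Auditory and visual impulse
trains $S_A(t)$, $S_V(t)$ are low-pass filtered with gamma-like kernels

$$f_{mod}(t) = t\, e^{-t/\tau_{mod}},$$

one time constant per modality ($\tau_A$, $\tau_V$).  Each of two
subunits delays one filtered input by a further stage with constant
$\tau_{AV}$ and multiplies it with the other:

$$S_1 = (f_{AV} * MCD_A)\cdot MCD_V, \qquad
  S_2 = (f_{AV} * MCD_V)\cdot MCD_A.$$

The *correlation* unit multiplies the subunits,
$MCD_{CORR} = S_1 \cdot S_2$, and codes the strength of audiovisual
temporal correlation; the *lag* unit subtracts them,
$MCD_{LAG} = -S_1 + S_2$, and codes the sign and size of the lag.  With
the sign convention as written, a vision-leading impulse pair yields a
positive time-averaged lag output; `mcd_respond()` verifies this against
a dense-grid numerical oracle in the test suite rather than assuming it.

Outputs are time-averaged over a 3-second window starting at the first
impulse — three times the one-second duration of the experimental
sequences — and z-scored across the stimulus set so that behavioral and
neural effect sizes are comparable.  Because each subunit is bilinear in
the inputs, scaling both inputs by $c$ scales the correlation output by
$c^4$ and the lag output by $c^2$; the z-scoring removes this
arbitrary-gain dependence.

### Numerical choices

* **Simulation rate.** Default 1 kHz.  Event timing has 10 ms
  granularity, and the time-averaged outputs at 1 kHz agree with a
  10 kHz brute-force convolution within 1 % (tested).  Convolutions are
  discrete FFT convolutions scaled by $1/\mathrm{rate}$, which makes the
  outputs rate-invariant.
* **Input encoding.** The model's input encoding is a design choice: by
  default each event is a unit-mass rectangular pulse of 10 ms — the
  physical duration of the clicks and flashes — with an on-grid delta
  available (`pulse = "delta"`).
* **Kernel truncation.** Kernels are truncated at $10\tau$, beyond which
  they hold less than $5\times10^{-4}$ of their mass.
* **Averaging window.** Half-open, $[t_\mathrm{first},
  t_\mathrm{first}+3\,\mathrm{s})$, so the sample count is exactly
  $3 \times \mathrm{rate}$.
* **z-scores.** Population (divide-by-$n$) convention, per participant
  when time constants differ per participant.

## Stimulus design

The experiment needs stimuli whose correlation and lag outputs vary
widely but are mutually uncorrelated, so that causality and
temporal-order judgments can dissociate.  `sample_sequence_pool()` draws
random sequences of 5 clicks and 5 flashes in one second (uniform onsets
with a 20 ms minimum within-modality gap, sampled exactly by the spacing
construction), `score_pool()` evaluates the detector on every candidate,
and `select_stimulus_set()` picks `k = 6` sequences with
$|\rho(\overline{CORR}, \overline{LAG})| < 0.2$.

The published procedure asked only for "a large range" of outputs; this
package makes that reproducible by maximizing the product of the ranges
of the two summaries subject to the correlation constraint.  Small
problems ($\binom{n}{k} \le 2\times10^5$ subsets) are solved by complete
enumeration; larger pools use greedy seeding from the four extreme
candidates plus a budgeted local swap search.  Scoring uses the
across-participant mean of the fitted time constants as the packaged
preset ($\tau_A = 68.9$, $\tau_V = 125.7$, $\tau_{AV} = 746.0$ ms),
since the original scoring parameters are not reprinted.  The packaged
six-sequence set under `inst/extdata/stimuli/` was selected from a
$10^4$-candidate pool with a fixed seed and has $|\rho| = 0.147$.

## Joint behavioral fit

Responses ("same cause", "visual first") are modelled with a
mixed-effects logistic regression: for each task,
$\mathrm{logit}\,P = \beta_0 + \beta_1 z + b_p$, where $z$ is the
z-scored correlation (causality) or lag (temporal order) summary and
$b_p \sim N(0, \sigma^2)$ a participant random intercept.  Seven fixed
parameters are fitted jointly: the three time constants, shared by both
tasks, and $(\beta_0, \beta_1)$ per task.  The source description of the
link parameters is internally inconsistent (task-dependent in one place,
task-independent in another); this package adopts task-dependent links
because only $3 + 2\times2 = 7$ matches the stated parameter count.  The
random-effects structure is an intercept per participant — the
explicitly specified structure.

* **Marginal likelihood.** Random intercepts are integrated out with
  adaptive Gauss–Hermite quadrature (15 nodes, mode-centred and
  curvature-scaled), implemented in the package and tested against a
  40-node non-adaptive oracle and dense numerical integration.
  `lme4::glmer` serves as an independent cross-check in the tests, never
  as the implementation.
* **Optimization.** A particle swarm explores the three log time
  constants with the link and variance parameters profiled out at every
  evaluation (an implementation device: the profiled objective has the
  same optimum as the joint one), followed by Nelder–Mead refinement of
  the full joint vector.  The procedure restarts `n_restarts` times
  (default 10, as published) and keeps the best likelihood; everything
  is deterministic given the seed.
* **Identifiability.** z-scoring leaves a shallow likelihood ridge along
  a common scaling of all three time constants; with few participants or
  trials the raw constants are recovered only loosely even though the
  psychometric fit is excellent.  At the study's size (13 participants,
  75 trials per stimulus and task) recovery of $\tau_V$ and $\tau_A$ is
  well within ±20 % provided enough restarts are used; the test suite
  uses 4 restarts there and 2 restarts for the 20-observer property
  check.
* **Goodness of fit.** The published $R^2$ definition is unstated; the
  package uses the squared Pearson correlation between predicted and
  observed per-stimulus response proportions per participant and task,
  matching the per-point scatter such studies display.  Task comparison
  is a paired t-test across participants.

## Observational power

`power_mc()` simulates full datasets (13 participants × 6 stimuli × 75
trials by default), refits the mixed logistic model to each with the
package's quadrature fitter, and tests the slope with a two-sided Wald
test at $\alpha = 0.05$ (the published criterion is unstated).  Power is
the fraction of significant simulations; its uncertainty is the exact
Clopper–Pearson binomial interval.  The intercept and random-intercept
spread of the simulated observers are not reported quantities; the
package uses $\beta_0 = 0$ and $\sigma_b = 0.5$, a typical
inter-individual spread for such tasks.  Note that a Clopper–Pearson
lower bound above 99.6 % is only reachable with roughly a thousand or
more all-successful simulations, so the acceptance script runs 5000 per
effect size.

## Evoked-response pipeline

Epochs span $[-200, +1800)$ ms around the first event at 250 Hz — 500
samples under the half-open convention adopted here (the source is
silent on the endpoint).  Trials are rejected when any channel's
peak-to-peak amplitude exceeds $2\times10^{-11}$ T.  Sensor triplets are
merged into virtual channels by a configurable weighted sum; the
vendor-specific field transformation behind the published
virtual-magnetometer mapping needs proprietary geometry, so synthetic
data are generated directly at the 102-channel level.  Band-pass
filtering (1–40 Hz zero-phase Butterworth) and decimation are provided
but are pass-throughs on the band-limited synthetic data.

Unisensory contamination is removed per sensor by regressing the task
evoked response on the auditory-only and visual-only localizer evoked
responses, pooled across all time points and stimuli (the pooling is the
adopted reading of an ambiguous description), and subtracting the fitted
weighted sum.  The regression has no intercept, is exact on noiseless
mixtures, idempotent, and warns on near-collinear localizer traces.

## Cluster statistics

Task contrasts are tested with paired t-maps over the 78 participant ×
stimulus pairs (df = 77), thresholded at $|t| > 2.6$ — the two-sided
critical value at $p = 0.01$ for df 77.  Supra-threshold samples are
grouped by sensor adjacency at equal times plus temporal adjacency on
the same sensor, separately by sign; cluster mass is the summed t.  The
null distribution of the maximum cluster mass comes from sign-flips of
the paired differences (equivalent to shuffling task labels within
pairs — the published description names only "label shuffling", and the
role of a covariance matrix in its cluster definition is unclear, so
plain adjacency clustering is used and documented as a divergence).
With $2^{n}$ below the permutation budget the enumeration is exhaustive,
which the tests exploit at $n = 3$ pairs.  Monte-Carlo p-values use the
add-one estimator.  A spatial-only variant corrects per-sensor encoding
score maps tested against zero.  Synthetic layouts use a planar grid
with 8-neighborhood adjacency; real layouts can be supplied as edge-list
CSVs.

## Model-based temporal response functions

Sensor time series are regressed on time-lagged copies of the four
detector component time courses (a finite-impulse-response convolution
model), per sensor, by ridge regression.  Folds leave out one stimulus
of one participant (78 folds at study scale); performance is the Pearson
correlation between predicted and recorded series, averaged over folds.
Per-component contributions zero all other components' weights before
predicting the held-out data; constant predictions score 0 by
convention, with a flag.

* **Lag window.** Unreported; default causal lags 0–500 ms,
  configurable.
* **Penalty.** Unreported; default nested cross-validation over a log
  grid within the training folds (split by stimulus), with a fixed-λ
  mode.  Predictors are centred with training-fold statistics.
* **Collinearity.** The detector components are strongly collinear on
  these stimuli (the lag unit can track the filtered visual input with
  $|r| > 0.99$), so individual lag-weight vectors are not identifiable
  from model-driven data even noiselessly, although predictions are.
  Weight-recovery tests therefore use well-conditioned white-noise
  predictors, while attribution tests use the collinear model-driven
  data and assert only the within- versus cross-component ordering —
  and one test asserts the overlap itself, mirroring the published
  caveat about correlated components.
* **Early/late split.** `windowed_scores()` rescores within 0–500 ms
  and 500–1000 ms sub-windows (fit unchanged), reproducing the
  supplementary-style split; an ambiguous-stimulus subset is available
  through the pipeline's `stimulus_subset` filter.

## Synthetic data

`ground_truth()` + `make_design()` + `simulate_observer()` +
`simulate_epochs()` generate datasets with the study's structure: 13
participants; per participant 2 tasks × 3 blocks × 25 repetitions of 6
sequences plus 2 passive localizer blocks per modality (1500 trials, 75
per stimulus per task), pseudo-random order with at most 3 consecutive
repeats.  Neural epochs are built as true response functions convolved
with the detector components, plus attenuation-weighted unisensory
evoked templates (damped-oscillation kernels on the event trains) whose
unattenuated versions populate the localizer epochs, plus white (or
optionally 1/f) noise scaled to a signal-to-noise variance ratio of 5 by
default.  The auto-generated response-function bank is rescaled so the
multisensory and unisensory parts carry equal average power — otherwise
one of them would be undetectable at any fixed noise level.  An
`orthogonalize_multisensory` switch projects the multisensory component
out of the unisensory span, making the separability assumption of the
removal regression exact; the default keeps the natural temporal
overlap.

What the generator does *not* emulate: real sensor noise spectra and
inter-sensor noise correlations, leadfield-based topographies, eye/heart
artifacts, head movement, or any vendor-specific acquisition detail.
Passing tests therefore demonstrate the correctness and calibration of
the algorithms under the stated generative assumptions, not performance
on real recordings.

## Problem sizes used in the tests

The test suite runs the full logic at reduced scale: candidate pools of
$10^4$ for the selection checks (smaller pools for properties that only
need a scored pool), 2–20 participants for fitting checks, 6–12 sensors
for the evoked/cluster/TRF stages, 200–400 permutations where an
exhaustive enumeration is not triggered, and 1200–5000 power
simulations.  These sizes were chosen once, as the smallest at which
each property is statistically decidable, and the methods above do not
change with scale.

## Known limitations

* The fitted $\tau_{AV}$ is only weakly constrained by behavior (the
  published per-participant values range over a factor of three), and
  the common-scale likelihood ridge makes all three constants jointly
  soft at small sample sizes.
* Real-data headline numbers (β = 1.80/1.02, R² = 0.92/0.81, sensor ρ
  maps, the 260–1250 ms cluster) require the deposited recordings; the
  package reads the same tabular formats and can be pointed at them,
  but nothing here asserts those values.
* The virtual-magnetometer merge is a weighted sum, not the
  field-transformation of the vendor tooling.
* Whether the weak correlation between the two judgments should be
  computed on trials or proportions is unreported;
  `cj_toj_correlation()` regresses per-participant-per-stimulus
  temporal-order proportions on causality proportions with a
  participant random intercept, and is flagged as an interpretation.
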