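---
title: "Self-relative evaluation of EEG-based identification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-relative evaluation of EEG-based identification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfrelEEG)
```

## The problem

EEG-based person identification extracts subject-specific structure from
multichannel brain signals and uses it as a biometric trait. The processing
chain implemented here is the classical autoregressive (AR) pipeline:

1. **Channel selection** — restrict the montage to an ordered set of `H`
   electrodes (`default_channel_set()` gives the conventional 19-electrode
   10--20 subset).
2. **Common average referencing (CAR)** — subtract the instantaneous
   cross-channel mean, removing reference drift shared by all electrodes.
3. **Butterworth band-pass filtering** — isolate one frequency sub-band
   (for example the canonical delta/theta/alpha/beta/gamma bands), either as
   a single causal forward pass or as a zero-phase forward--backward pass.
4. **Static overlapped segmentation** — cut the recording of duration `V`
   into windows of length `v` with overlap fraction `alpha`; only complete
   windows count, so `N = floor((V - v) / (v (1 - alpha))) + 1`. With the
   default `V = 60` s, `v = 5` s, `alpha = 0.4` this yields 19 segments.
5. **Burg AR features** — fit an order-`Q` AR model per channel per segment
   by Burg's method and concatenate the per-channel coefficient blocks into
   one identity vector of dimension `d = H * Q`.
6. **Classification** — k-nearest neighbours on Euclidean distance by
   default (`k = 1`), with naive Bayes, a decision tree and LDA available
   behind the same contract, scored by stratified k-fold cross-validation.

A configuration that looks best at a fixed population size may degrade
fastest as new subjects enroll. The package therefore evaluates every cell
of a (filter order, sub-band) grid under an **openness condition**: the
enrolled population grows step by step in random increments and the
classifier is refit from scratch at each step (repetitive batch learning).
Each cell is then scored not by raw accuracy but by **self-relative**
degradation metrics — the system is compared against itself across steps:

* `lrl(oam)` — local relative loss: mean relative accuracy drop between
  successive steps, moving reference, in percent.
* `grl(oam)` — global relative loss: mean relative drop of every step
  versus the first step, in percent.
* `power_ratio(g)` — max/min ratio of marginal mean GRL across the values
  of one target parameter; a large power means that parameter diversifies
  the quality of identity information.
* `dmm(acc, grl)` — decision-making metric, `accuracy / GRL` with GRL in
  percent; maximizing it selects the configuration that combines high
  accuracy with low degradation.

In both losses, a step only contributes when the reference accuracy exceeds
the step accuracy; non-degrading steps are clamped to zero and kept in the
denominator (over all `R - 1` transitions), so configurations with
different numbers of degrading steps stay comparable. Set
`degrading_only = TRUE` to average over degrading transitions only. When a
configuration never degrades its GRL is 0 and the DMM is reported as `NA`
(undefined, not infinite).

## The openness simulation

`openness_config()` describes a ladder of population sizes from `t1` to
`tr` over `steps` steps. Increments are drawn from a binomial law
`Binomial(step_trials, step_prob)` with zeros redrawn (every step must
enroll at least one novel subject) and whole increment vectors are
rejection-sampled until they sum to `tr - t1`, so the size sequence is
strictly increasing with exact endpoints. `sequences` independent nested
label sequences are drawn over the available `E` subjects; `tr < E` keeps
the system open at the last step. Every sequence uses its own deterministic
sub-stream of the master seed, so adding sequences never perturbs earlier
ones.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(synthetic_cohort_spec(
  n_subjects = 12, n_channels = 6, duration = 60,
  identity_band = c(30, 50), seed = 1))
cfg <- pipeline_config(channel_set = sprintf("Ch%02d", 1:6),
                       duration = 60, ar_order = 2)
fit <- self_relative_eval(cohort, cfg,
  sweep = sweep_spec(orders = c(2, 4),
                     bands = list(c(0.5, 4), c(4, 8), c(8, 13),
                                  c(13, 30), c(30, 50))),
  openness = list(t1 = 3, tr = 10, steps = 5, step_trials = 100,
                  step_prob = 0.02, sequences = 3),
  seed = 1)
summary(fit)
plot(fit)
```

The identity structure was planted in the 30--50 Hz band, and the fit's
`report$best` cell recovers that band as the argmax-DMM configuration.

## The synthetic cohort generator

Real resting-state archives cannot be assumed available, so the package
ships a generator whose defaults *are* its study conditions. Each subject's
channel signal is the sum of three parts:

* a **shared background**: a stationary AR process with deterministic
  low-frequency poles (modest radius 0.6, pole frequencies spread over
  2--12 Hz), identical for all subjects — it models the common rhythmic
  floor that carries no identity;
* a **subject-specific resonance**: an AR(2) process with one conjugate
  pole pair inside `identity_band`. Pole frequencies and radii are drawn by
  stratified sampling (one draw per equal-width bin, in random order), so
  subjects are spread across the band without chance clustering. The
  frequency span is `0.8 * separability` of the band half-width and the
  radius is `0.92 ± 0.03 * separability`. One innovation stream per subject
  drives all of that subject's channels, which receive it through a fixed
  spatial gain pattern (`Unif(0.3, 1.7)` per channel) plus a small
  per-channel pole-frequency jitter — both drawn once per cohort, so CAR
  attenuates but cannot cancel the component, and `separability = 0` yields
  identical ground truth for every subject. The component is band-limited
  by a fixed zero-phase Butterworth(4) filter on `identity_band` and scaled
  to amplitude `6 * separability` relative to unit noise;
* **white measurement noise** per channel (`noise_sd`, default 1).

Two design choices deserve an explanation:

**Why band-limit an already narrowband resonance?** An AR(2) resonance has
spectral tails far outside its band, and the *relative* height of a
spectral peak over the local floor is invariant under any linear filter.
Without band-limiting, an analysis pipeline tuned to a *different* band
still sees the planted peak in its pass-band tails, and spare AR
coefficients lock onto it — off-band configurations become spuriously
competitive and the planted band no longer dominates. Confining the
subject component to its band restores the physically intended situation:
outside `identity_band` all subjects look alike.

**Why does `separability` gate the amplitude as well as the dispersion?**
`separability = 0` is the degenerate null cohort — all subjects must be
statistically identical *and* indistinguishable from a cohort that never
had an identity component, so that null-cohort accuracy sits at chance and
the in-band power fraction drops to the background level. Scaling both the
pole dispersion and the component amplitude with one knob achieves this
with a single monotone parameter.

What the generator does **not** emulate: non-stationarity across a
session, eye-blink and muscle artifacts, volume-conduction mixing beyond a
static gain pattern, inter-session variability, and realistic 1/f spectral
slopes. It is a construction for exercising band selection and
degradation metrics, not a forward model of EEG physics.

## Scaled study conditions

Desk-scale runs use conditions chosen once and kept fixed:

* cohort `E = 12` subjects, `H = 6` channels, 60 s at 160 Hz,
  `identity_band = c(30, 50)`, `separability = 1`, `noise_sd = 1`;
* openness ladder `t1 = 3` to `tr = 10` over 5 steps, increments from
  `Binomial(100, 0.02)`, `M = 3` sequences (for `E = 10` cohorts the
  ladder tops out at `tr = 9`, since the last step must stay open);
* analysis grid: Butterworth orders `{2, 4}` by the five canonical bands;
  analysis AR order `Q = 2`, 1-NN classification, 3-fold stratified CV.

`Q = 2` matches the order of the planted AR(2) identity component: the two
coefficients per channel are the sufficient statistic for the planted pole,
and higher orders spend coefficients on the background process, diluting
the Euclidean feature geometry at this small scale. (At full scale, with
more channels and longer recordings, larger `Q` is the conventional
choice; the package default is `Q = 12`.)

## Numerical conventions

* Burg coefficients follow the convention in which `x_t` is predicted by
  `+ sum_i a_i x_(t-i)` (the same as `stats::ar.burg`, which serves as the
  independent cross-check in the tests). Series are mean-centered; the
  model has no intercept.
* The segment count uses floor semantics: only windows that fit entirely
  inside the recording are produced, and the hop must land on a sample
  boundary.
* Step accuracy is micro-averaged: total correct over total predictions
  pooled across folds, which equals the fold-accuracy mean for equal-sized
  folds. Per-fold accuracies are stored alongside.
* Power is `max/min` of the marginal GRL means, and is undefined (reported
  `NA`) for a margin with a single value or a zero mean.
* Filter designs are checked for stability (all denominator roots strictly
  inside the unit circle) and rejected, never clipped.

## Reproducibility

Every stochastic stage (cohort generation, size sequence, label sequences,
fold shuffles) runs under its own deterministic sub-stream of one master
seed and restores the caller's RNG state. `run_all()` persists every
intermediate — per-cell feature CSVs, the openness simulation JSON,
per-cell accuracy CSVs, the metric report and a manifest — so any stage
can be replayed bit-exactly, and `report_from_results()` recomputes the
full report from the persisted accuracies alone.
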