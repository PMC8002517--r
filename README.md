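# selfrelEEG

Self-relative evaluation of EEG-based biometric identification systems.

EEG-based person identification extracts subject-specific structure from
multichannel brain signals with a parameterized pipeline — common average
referencing, Butterworth band-pass filtering into a frequency sub-band,
static overlapped segmentation, Burg autoregressive (AR) features, and a
classifier. The configuration that scores best at a *fixed* population
size is not necessarily the one that holds up as new subjects enroll.

`selfrelEEG` evaluates every cell of a (filter order, frequency sub-band)
grid under an **openness condition**: the enrolled population grows step by
step in random binomial increments, the classifier is refit from scratch at
every step, and each configuration is scored by how it degrades relative to
itself:

* **LRL** — local relative loss (step-to-step, moving reference, percent),
* **GRL** — global relative loss (every step versus the first, percent),
* **Power** — max/min ratio of marginal mean GRL across a parameter's
  values (how strongly the parameter diversifies identity information),
* **DMM** — decision-making metric, accuracy divided by GRL; maximizing it
  selects the configuration carrying the most *robust* identity
  information.

The package ships a synthetic multichannel cohort generator whose subject
identity is planted as band-localized AR dynamics (so everything is
exercisable without data downloads), plus minimal EDF input/output for real
resting-state recordings.

## Worked example

Generate a 12-subject cohort with identity planted in the 30–50 Hz band,
then ask the framework which (order, band) configuration carries the most
robust identity information:

```r
library(selfrelEEG)

cohort <- generate_cohort(synthetic_cohort_spec(
  n_subjects = 12, n_channels = 6, duration = 60,
  identity_band = c(30, 50), seed = 1))

cfg <- pipeline_config(channel_set = sprintf("Ch%02d", 1:6),
                       duration = 60, ar_order = 2)

fit <- self_relative_eval(cohort, cfg,
  sweep = sweep_spec(orders = c(2, 4),
                     bands = list(c(8, 13), c(13, 30), c(30, 50))),
  openness = list(t1 = 3, tr = 10, steps = 5, step_trials = 100,
                  step_prob = 0.02, sequences = 3),
  seed = 1)

summary(fit)
```

```
Self-relative evaluation
  grid: 6 configuration(s); openness 3 -> 10 subjects over 5 steps, 3 sequence(s)
  best configuration: order 4, band [30, 50] Hz (DMM = 0.201, GRL = 4.56%)

Per-configuration metrics:
 config_id filter_order band_low band_high filter_variant acc_first acc_last
  o2_b8-13            2        8        13         causal     0.608    0.281
 o2_b13-30            2       13        30         causal     0.883    0.730
 o2_b30-50            2       30        50         causal     1.000    0.898
  o4_b8-13            4        8        13         causal     0.351    0.207
 o4_b13-30            4       13        30         causal     0.830    0.642
 o4_b30-50            4       30        50         causal     0.994    0.914
    lrl    grl dmm_last
 16.638 41.754    0.007
  4.893 12.196    0.060
  2.624  5.794    0.155
 11.946 28.554    0.007
  6.138 14.255    0.045
  2.210  4.557    0.201

Self-relative report: 6 configuration(s)

Mean GRL (%) per filter order:
     2      4
19.915 15.788
  power: 1.26

Mean GRL (%) per sub-band:
 [8, 13] [13, 30] [30, 50]
  35.154   13.225    5.175
  power: 6.79

Best configuration (max last-step DMM): o4_b30-50 (DMM = 0.201, GRL = 4.56%)
```

The planted 30–50 Hz band is recovered: it has both the lowest degradation
(GRL 4.6% versus 29–42% for the mismatched alpha band) and the highest
DMM. `plot(fit)` draws the mean accuracy-versus-population curves, one per
configuration.

## Running from a configuration file

A whole study — cohort, sweep, openness simulation, report — can be driven
from one YAML file and replayed bit-exactly:

```r
run_all("config.yaml", "results/")      # persists features/, accuracy/,
                                        # openness.json, report/, manifest.json
report_from_results("results/")         # metric-only rerun from the CSVs
```

or from the shell via the shipped front end:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "selfrelEEG", package = "selfrelEEG"))') \
  run-all --config config.yaml --out results/
```

Real recordings enter through `read_edf()` / `read_cohort_edf()` (one EDF
file per subject) in place of the `input.synthetic` block.

## Documentation

The methods vignette (`vignettes/self-relative-evaluation.Rmd`) documents
the evaluation framework, the synthetic generator's construction and the
reasoning behind every frozen numerical choice.
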