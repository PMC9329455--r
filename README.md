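# huangnet

Standardized classification of continuous behavioral and
electrophysiological recordings with **two-hidden-layer feedforward
networks whose widths are fixed in closed form**. The package is aimed
at researchers who want a reproducible, expert-free classifier for
problems like six-category joystick behavior in a virtual T-maze or
artifact-vs-signal triage of EEG independent components — settings
where hand scoring drifts between raters and simple threshold rules
stop scaling.

## The method

Given `N` distinct training samples and `m` output classes, Huang's
construction guarantees learnability with two hidden layers of sizes

```
layer 1:  sqrt((m + 2) N) + 2 sqrt(N / (m + 2))
layer 2:  m sqrt(N / (m + 2))
```

each rounded up to a whole neuron. For the T-maze problem (`N = 5400`,
`m = 6`) that is 259.81 → **260** and 155.88 → **156** neurons; for the
EEG component problem (`N = 1632`, `m = 2`) it is 121.19 → 122 and
40.40 → 41.

The classifier is `softmax(W3 tanh(W2 tanh(W1 x + b1) + b2) + b3)`,
trained full-batch with exact backpropagated gradients by either
scaled conjugate gradient (`scg`) or resilient backpropagation
(`rprop`), under a 70/15/15 train/validation/test split. Training
stops when a configurable number of validation cases (100, 150 or 200
at study scale) is classified correctly *in a row* within one
fixed-order validation pass. At decision time a category is selected
only if its probability exceeds a threshold just above chance (0.17
for six classes); otherwise the trial is counted as *missed*.

Around the model the package provides:

* the expert rule system labeling T-maze trajectories (fleeing,
  approach safety left/right, reaching out left/right, behavioral
  conflict), used both as label generator and reference classifier;
* builders for the study's input vectors (6003-element trajectory
  vector; 1603-element component vector of time-course, topography and
  1–70 Hz band spectrum);
* seeded synthetic-data generators for both problems;
* the evaluation battery: one-vs-rest confusion counts and metrics,
  ROC points, missed-trial counting, McNemar paired comparisons, and a
  model-selection grid over trainers and stopping settings.

## Worked example

```r
library(huangnet)

huang_layer_sizes(5400, 6)
#> layer1 layer2
#>    260    156

sim <- simulate_tmaze_dataset(trajectory_sim_config(
  n_participants = 12, trials_per_condition = 4, seed = 42))
fit <- ffnet(tmaze_features(sim), sim$labels, algorithm = "scg",
             consecutive_correct = 25, max_epochs = 400, seed = 7)
fit
#> Two-hidden-layer feedforward classifier (scg)
#>   architecture: 6003 -> 46 -> 28 -> 6
#>   epochs: 3 (stop: validation_run)
#>   accuracy: train 100.0%, validation 97.2%, test 100.0%

dec <- predict(fit, tmaze_features(sim), type = "decision")
count_missed(dec)
#> [1] 0
```

The 240 simulated trials (12 participants, 5 conditions, 4 trials
each) yield a training split of 168 cases, so the Huang sizes are 46
and 28 neurons. Training stopped after 3 full-batch epochs because 25
consecutive validation trials were classified correctly; every
held-out test trial was then classified correctly, and no trial's top
probability fell below the 0.17 selection threshold. `summary(fit)`
adds per-class one-vs-rest precision, true/false-positive rates and
accuracy on the test split; `plot(fit)` shows the loss and validation
history.

The same surface handles the EEG component problem:

```r
ic  <- simulate_ic_dataset(ic_sim_config(n_participants = 16, seed = 42))
fit <- ffnet(ic_features(ic), ic$labels, consecutive_correct = 25)
```

A thin command-line wrapper (`inst/cli/huangnet`) exposes `size`,
`simulate`, `label`, `train`, `evaluate` and `compare` subcommands
over the same functions.

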