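---
title: "Closed-form sized feedforward classifiers for behavioral and EEG component data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-form sized feedforward classifiers for behavioral and EEG component data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huangnet)
```

## The model and its assumptions

`huangnet` implements a deliberately rigid classifier: a feedforward
network with exactly two hidden layers whose widths are not tuned but
fixed in closed form from the number of distinct training samples $N$
and the number of output classes $m$:

$$L_1 = \left\lceil \sqrt{(m+2)N} + 2\sqrt{\tfrac{N}{m+2}} \right\rceil,
\qquad
L_2 = \left\lceil m\sqrt{\tfrac{N}{m+2}} \right\rceil.$$

Huang's constructive result guarantees that a two-hidden-layer network
of these sizes can represent any labeling of $N$ distinct samples with
$m$ outputs, which is exactly the property a standardized analysis
pipeline needs: the architecture is a function of the dataset, not of
the analyst. The ceiling is used for rounding so the guarantee is
never undershot by a fractional neuron; with $N = 5400$, $m = 6$ the
raw values 259.81 and 155.88 become 260 and 156.

```{r}
huang_raw_sizes(5400, 6)
huang_layer_sizes(5400, 6)
```

The forward model is
$\mathrm{softmax}(W_3\tanh(W_2\tanh(W_1x+b_1)+b_2)+b_3)$. The source
problem statement fixes the architecture and the two trainers but not
the output nonlinearity or the loss; we use the standard
pattern-classification pairing of a softmax output with cross-entropy
loss. This choice is what makes the 0.17 decision threshold
meaningful: outputs are class probabilities, and 0.17 sits just above
the six-class chance level $1/6 = 0.1667$. Gradients are exact
reverse-mode derivatives, verified against central finite differences
in the test suite.

Three further choices fill documented gaps:

* **Initialization.** Weights are uniform in
  $\pm\sqrt{6/(\mathrm{fan_{in}}+\mathrm{fan_{out}})}$, biases zero.
  This keeps early tanh activations in their linear range and makes
  every fit a pure function of the seed.
* **Standardization.** Each input feature is z-scored with center and
  scale estimated *on the training split only*. The 6003-element
  trajectory vector mixes $[-1,1]$ deflections with raw participant,
  trial and condition ids; unscaled, the id columns would dominate
  the early epochs. Constant features get unit scale.
* **Full-batch training.** Both trainers operate on the full training
  split per epoch: Rprop is defined full-batch, and the scaled
  conjugate gradient algorithm is implemented as published (scalar
  second-order estimate along the search direction, Levenberg-style
  damping, restart to steepest descent every $P$ steps for $P$
  parameters). Trainer constants are the published defaults
  ($\sigma = 5\times 10^{-5}$, $\lambda_0 = 5\times 10^{-7}$ for SCG;
  $\eta^+ = 1.2$, $\eta^- = 0.5$, $\Delta_0 = 0.07$,
  $\Delta_{max} = 50$ for Rprop, the iRprop$^-$ variant that skips the
  pending update on a gradient sign flip).

## The stopping protocol

Data are split 70/15/15 into training, validation and test sets by a
seeded shuffle (validation and test take $\lfloor 0.15 n\rfloor$ cases
each, the remainder trains). Training stops when at least $k$
consecutive validation cases — $k \in \{100, 150, 200\}$ at study
scale — are classified correctly (argmax rule) within one pass over
the validation split. Two readings of "in a row" are possible: within
one fixed-order pass, or across epochs. We implement the within-pass
reading with a single seeded validation order reused every epoch,
which makes the criterion well defined and reproducible; requiring
$k$ larger than the validation split is rejected as a configuration
error rather than silently never firing. An epoch cap and a
gradient-norm tolerance act as safety stops, since nothing otherwise
guarantees termination. The thresholded selection rule (probability
$> 0.17$, else *missed*) is an evaluation-time device only; using it
during training would conflate convergence with calibration.

## The behavioral rule system

The six T-maze categories are implemented as fixed thresholds on the
joystick range (device maximum = 1.0), not on per-participant empirical
maxima — the criteria are stated as fractions of the possible
excursion. With 3000 samples covering 13 s (230.8 Hz), the "first 8 s"
is 1846 samples and the "first 4 s" 923.

Three operationalizations were genuinely open and are settled as
follows:

* **Sustained crossings.** Each threshold must hold for a dwell
  fraction (default 20%) of its window; single-sample crossings would
  make the rules brittle under noise. The fraction is a parameter of
  `rule_params()`.
* **Precedence.** Latency-conflict is checked first (onset later than
  1.5 s), then reaching out, fleeing, approach safety, and finally
  conflict by behavior switch or bad performance; anything left is
  unclassified. The order makes the categories mutually exclusive.
* **"Very bad performance."** Operationalized as a robust outlier
  rule: a trial's roughness (mean absolute per-sample change of both
  axes) more than 3 robust standard deviations (1.4826 MAD) above the
  participant's median. This is a documented stand-in for an
  undefined expert judgment and is fully configurable.

Turn direction (left vs right variants of approach safety and
reaching) is the sign of $x$ at the sample of largest $|x|$ in the
first 8 s; mirroring $x$ provably swaps labels 2↔3 and 4↔5 and fixes
1 and 6, a property the suite tests.

## What the synthetic generators emulate — and what they do not

The trajectory generator reproduces the *structure* of the study data
(participants × 5 conditions × trials, 3000 + 3000 samples in
$[-1,1]$) and emits parameterized ramp templates built to satisfy one
rule each, plus onset jitter (mean 0.5 s, sd 0.15 s, clipped to
[0.1, 1.2] s) and additive Gaussian noise (default sd 0.02 of full
deflection). Conflict trials mix three mechanistic variants mirroring
the three conflict triggers: late onset (1.8–3.0 s), a mid-trial
backward-to-forward switch, and a "sloppy" high-jitter switch. The
per-condition category mix is our own choice (no distributional facts
about the original trials are published beyond counts): negative cues
favor fleeing/approach-safety, positive and approach–approach cues
favor reaching, ambiguous cues carry the most conflict.

The component generator likewise fixes seven kind recipes (blink,
lateral eye, muscle, pulse, line noise; posterior alpha,
broadband 1/f) over the feature triple, with a fixed-index montage
semantics (frontal 1–4, temporal 13–20, posterior 25–32, edge ring)
instead of real electrode coordinates, and a default artifact
fraction of 0.6, consistent with the roughly 60/40 artifact balance
implied by the published component counts.

These generators are *not* simulations of virtual-reality physics or
of mixed EEG: trajectories are splines, not control dynamics, and
components are drawn directly in feature space. Passing tests
therefore demonstrate that the pipeline — rules, sizing, trainers,
evaluation — is internally correct and learnable, not that the
published accuracies on the deposited datasets are reproduced. The
published headline accuracies (96.2–98.4% behavioral, 88.8–94.6%
component) depend on those datasets; the package's end-to-end checks
use desk-scale analogues instead (12 × 5 × 4 = 240 trials and 16 × 32
= 512 components, validation-run length 25 scaled to the 36- and
76-case validation splits), where SCG-trained Huang-sized networks
reach ≥ 95% (six-class) and ≥ 90% (two-class) held-out accuracy.

## Evaluation conventions

* Missed trials (no probability above threshold) are excluded from
  confusion counts and reported separately — the published per-class
  totals of 5396 rather than 5400 counted trials are consistent with
  exactly this exclusion. The behavior is documented in
  `confusion_counts()`.
* Percentages are rounded half away from zero to one decimal; this
  reproduces every printed metric in the shipped reference tables,
  where banker's rounding would not.
* The McNemar statistic is $(b-c)^2/(b+c)$ *without* continuity
  correction: discordant counts (3, 10) give 3.769 exactly, the
  printed value; the corrected statistic would be 2.769.
* ROC curves sweep all distinct scores as thresholds and include both
  endpoints; ties in `select_category()` break toward the lowest
  class index (the source is silent; any fixed rule would do, an
  explicit one makes runs comparable).
* The model-selection grid flags the best network in two stages, as
  in the original selection narrative: the top-accuracy row, then any
  row whose paired McNemar statistic against it is below 3.841
  remains in contention, and the fewest missed trials on the first
  new dataset decides.

## Numerical choices and degenerate inputs

Probabilities are computed with max-shifted softmax; the loss clamps
probabilities at $10^{-300}$ so a confidently wrong prediction yields
a large finite loss. A stationary start (zero gradient) terminates
immediately with reason `gradient_tolerance` and unchanged weights.
Zero-variance features standardize with unit scale. The spectrum
builder averages one-second rectangular periodogram segments, giving
exactly 1 Hz bins, and requires a sampling rate of at least 140 Hz so
the 70 Hz band is below Nyquist. Model files are a single serialized
container with a format-version tag and round-trip bit-exactly.

## Known limitations

* The rule system's dwell semantics and outlier score are principled
  but not validated against expert raters; treat relabeled real data
  with care.
* Huang sizing guarantees representational capacity, not
  generalization; at study scale the network is heavily
  over-parameterized and the consecutive-correct rule is the only
  regularizer, exactly as in the original protocol.
* The generators' class templates are well separated by construction;
  real joystick and EEG data are harder, and accuracy on them should
  be established per dataset.
* Training is single-threaded, full-batch, dense linear algebra; at
  the full 5400 × 6003 scale with 260/156 hidden units a fit is
  minutes-scale, not seconds-scale.
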