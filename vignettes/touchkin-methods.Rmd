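---
title: "Methods: simulating, featurizing and classifying tablet dragging movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, featurizing and classifying tablet dragging movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children dragging cards across a tablet leave a dense motor trace: 40
coordinate pairs per second from the first tap to the moment the finger
lifts. Autistic children's dragging movements tend to differ from those of
typically developing peers in characteristic directions — less straight,
more frequent changes of direction, shorter and more fragmented bouts, and
faster but more variable speed. `touchkin` packages the full computational
chain for studying such a motor signature: a synthetic cohort generator with
those contrasts planted, finite-trajectory segmentation, per-task kinematic
feature extraction, a small feedforward classifier with a repeated
cross-validation protocol, and a greedy input-ablation importance analysis.

Because no public touch-log dataset of this design exists, the synthetic
generator is a first-class module: it provides the *stated world* in which
every downstream stage can be tested end to end.

## The synthetic world

Each subject is described by six latent motor parameters (see
`?group_effect_preset`): `base_speed`, `speed_cv`, `heading_noise_sd`,
`goal_gain`, `fragmentation_rate` and `accel_burst_sd`. A drag is simulated
as a **goal-attracted correlated walk** at 40 Hz on a 1280 x 800 screen:
the new heading is the angle of the convex combination of the unit vectors
toward the goal (weight `goal_gain`) and along the previous heading, plus
Gaussian jitter; the step length is speed/40, with speed following a smooth
bell profile scaled by `base_speed`, multiplied by lognormal noise of
coefficient of variation `speed_cv`, plus additive acceleration bursts.
Finger lifts arrive as a Poisson process with mean `fragmentation_rate` per
drag; each lift splits the drag into separate finite trajectories. Angles
are blended through unit vectors (not raw radians) so the combination is
well defined across the wrap-around at ±pi.

The `"default"` preset plants the group contrasts in the directions reported
for real cohorts: the ASD-like group has lower `goal_gain` (lower
straightness), higher `heading_noise_sd` (more directional change), higher
`fragmentation_rate` (shorter, more numerous bouts), and higher `base_speed`,
`speed_cv` and `accel_burst_sd` (higher mean and maximum speed but lower
minimum speed, wider acceleration spread). The `"null"` preset gives both
groups the TD-like distribution, for chance-level calibration. The numeric
values live in `group_effect_preset()`; effect sizes were chosen once so the
planted preset supports cross-validated accuracy above 0.9 downstream while
the null preset sits at chance — the planted-signal regime the design calls
for — and are not tuned thereafter.

What the generator does **not** emulate: real bout duration/length scales
(no published quantities exist to match), device noise, finger-size
occlusion, task comprehension, or any cognitive correctness of performance.
A green planted-signal test therefore establishes that the pipeline recovers
a signal of the stated shape and size — not that real cohorts carry such a
signal.

## Finite trajectories

A *finite trajectory* is the run of samples from a press to the subsequent
release, inclusive. Segmentation keeps every episode with at least
`min_points = 2` samples (a speed needs two points); shorter episodes are
dropped into an auditable discard log rather than silently. Moves outside
any press-release episode are discarded with a warning (device noise); a
release without an open press is a hard, indexed error. No smoothing,
resampling or interpolation is applied anywhere.

## The 12 kinematic features

Per step: speed is displacement over the time difference (forward
differences); acceleration is the signed derivative of scalar speed;
heading is the `atan2` of the displacement; directional change (DC) is the
absolute wrapped heading difference per unit time (radians/s, wrapped to
(-pi, pi], so one step's DC never exceeds pi/dt). Zero-length steps have
speed 0 and propagate the previous heading.

Per task, features are computed per trajectory and then averaged:
`MeanSpeed`, `MeanAcceleration` and `DC` are means over trajectories of the
per-trajectory means; `MaxSpeed`, `MinSpeed`, `MaxAcceleration` and
`MinAcceleration` are means of per-trajectory extrema ("average peaks");
`STH` (straightness: net displacement over path length) is the mean of
per-trajectory straightness; `MeanLength` is the mean per-trajectory path
length. The per-trajectory-then-average convention is deliberate: averaging
pooled steps instead would break `MinSpeed <= MeanSpeed <= MaxSpeed`
whenever bout lengths differ, because the extrema are per-trajectory means.
The SD features (`sdSpeed`, `sdAcceleration`, `sdDC`) are sample SDs over
all steps pooled across the task — they describe the spread of values
collected during the task, not between-bout variation. Sample SDs (n - 1)
are used everywhere, including the standardizer.

`MeanLength` deserves a note: one published description reads "average
amount of finite trajectories", another "average length of trajectories".
We implement the length reading and carry the per-task trajectory *count*
as the auxiliary diagnostic column `n_trajectories`, excluded from the
model inputs. Features undefined on short bouts (DC and acceleration need
three points) are excluded from that feature's aggregate rather than
zero-filled, which would bias DC downward.

Each sample is 12 kinematic features plus 5 subtest indicator columns
(exactly one equal to 1), standardized on the kinematic columns only.

## The classifier and its protocol

A 17-H-2 multilayer perceptron: tanh hidden layer (default H = 5), softmax
output, Xavier-uniform initialization (limits `sqrt(6/(fan_in+fan_out))`),
zero biases, trained with Adam (defaults beta1 0.9, beta2 0.999, eps 1e-8)
at learning rate 0.01 for 500 epochs on the cross-entropy of integer labels
(ASD = 0, TD = 1; one-hot targets and sparse integer labels are the same
loss). Batch size is unspecified in the protocol we replicate; we use
**full-batch** gradient descent, the smallest-deviation choice, which also
makes training exactly deterministic given the seed. Divergence (non-finite
loss) raises an error naming the epoch.

Model selection uses 10-fold cross-validation with 5 repetitions. Two
documented choices matter:

* **Split mode.** The stated protocol randomizes over samples, so one
  subject's 25 tasks may land in both train and test folds. This leaks
  subject identity: on *null*-preset data (identical group distributions)
  the sample-level split yields accuracies well above chance, because the
  network can memorize each subject's latent-parameter signature. The
  package therefore implements both `split_mode = "sample"` (the default,
  replicating the protocol) and `"subject"` (leakage-safe). Chance
  calibration is asserted under the subject split, which is the correct
  null; the leakage of the sample split is surfaced, not silently fixed.
* **Standardization scope.** The stated order standardizes the whole
  dataset before splitting (`scope = "global"`, default); a leakage-safe
  `"per_fold"` mode fits the scaler on each training split only.

The hidden-layer size is chosen by a descending grid search (10 down to 2):
the smallest H whose mean CV accuracy is within 1 percentage point
(configurable) of the best candidate wins — an operationalization of
"comparable accuracies, keep the model simple". The best fold-model is the
one with the highest held-out accuracy across all k x repetitions models,
ties broken by scan order (earlier repetition, then earlier fold).

## Backward input ablation

Feature importance uses greedy backward elimination on a *trained* network,
never retraining: "removing an input neuron" is implemented by fixing that
standardized input at 0, its expected value, which is weight-equivalent to
severing the neuron's contribution at its mean. Each round masks every
remaining kinematic feature in turn, permanently removes the one whose
removal leaves accuracy highest (ties: higher sensitivity, then fixed column
order), and records accuracy/sensitivity/specificity. The five subtest
indicators are never candidates. The curve has one row per retained count
from 12 (unmasked, metrics equal to plain evaluation exactly) down to 1; the
all-masked floor (indicators only, ~chance on group-balanced tasks) is kept
as an attribute. The default evaluation set is the best model's held-out
fold — the defensible choice when the protocol is silent — with
whole-dataset evaluation available for diagnostics.

## Determinism and numerical choices

A single master seed is fanned out to per-stage and per-subject seeds by a
polynomial hash (`derive_seed()`), so any stage can be re-run in isolation.
All artifacts are plain text (CSV, key-value, JSON); the run manifest
records the config hash and per-artifact MD5 checksums, and identical
configs reproduce identical checksums end to end. Softmax subtracts the
row maximum before exponentiation; probabilities are floored at 1e-300
inside the log loss; angle wrapping maps to the half-open interval
(-pi, pi] so a 180-degree reversal is pi/dt exactly.

## Known limitations

* The simulator's kinematic scales (speeds, durations) are stated
  assumptions, not measured quantities; only the contrast *directions* are
  anchored in published findings.
* Planted-signal accuracy in the default preset is near-ceiling; it tests
  recovery, not realistic difficulty.
* The sample-level CV default reproduces a protocol that leaks subject
  identity; conclusions about generalization to new subjects require
  `split_mode = "subject"`.
* Ablation importance is evaluation-set dependent; with a 150-sample
  held-out fold the metric differences between weak features can be within
  sampling error, so removal orders are stable only for strong features.
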