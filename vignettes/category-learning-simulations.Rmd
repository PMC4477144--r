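---
title: "Simulating heterogeneous perceptual category learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating heterogeneous perceptual category learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protodist)
```

## The task and the phenomenon

`protodist` implements a complete, testable pipeline for studying
prototype-distortion category learning of the kind used with high-functioning
autistic and typically developing children. A category is defined by a
*prototype*: a shape built from nine dots connected in the order they were
drawn and filled as a closed polygon. Category members are *distortions* of
the prototype, produced by probabilistically displacing the dots; the larger
the displacement probability, the higher the distortion level (L2 through
L7). Non-members are *random foils*: nine-dot shapes generated independently
of the prototype.

In the A/not-A task a learner is trained with feedback to accept members and
reject foils, then tested without feedback on 60 items: 5 presentations of
the (never-trained) prototype, 5 novel distortions at each of L2, L3, L4, L5
and L7, and 30 novel foils. The proportion of "member" responses
(*endorsements*) per stimulus class is the generalization profile. Typical
learners show a monotone gradient — highest endorsement of the prototype,
falling with distortion level, lowest for foils. A reliably identifiable
subset of autistic children instead shows a flat, depressed profile with
elevated foil endorsement; endorsing 30% or more of the random foils is the
operational criterion for this "Type II" profile, and children frequently
switch between the two profiles across tasks.

The package provides every stage as a first-class, seeded component:
stimulus generation (`generate_prototype()`, `distort()`,
`generate_random_foil()`), encoding (`render()`), training regimens and test
sets (`build_regimen()`, `build_test_set()`), the connectionist learner
(`init_network()`, `train_network()`, `calibrate_endorsement()`,
`endorse()`), orchestration (`run_condition()`,
`run_within_subject_battery()`, `mixture_profile()`), behavioral
classification (`classify_profile()`, `apply_exclusions()`,
`switch_table()`), and a synthetic cohort generator
(`generate_cohort()`, `recover_parameters()`) that stands in for human data
so the whole analysis chain is testable end to end.

## Stimulus model

Dots live on a 50 x 50 unit canvas; the nine prototype (and foil) dots are
drawn uniformly without replacement from the integer grid of the central
30 x 30 region, leaving a 10-unit margin so displaced dots rarely reach the
edge. Canvas dimensions are not dictated by the behavioral task itself; the
defaults follow the classic dot-pattern convention and are configurable
through `canvas_spec()`.

A distortion level is a probability vector over five concentric displacement
annuli: no move, then bands at 1–2, 2–3, 3–4 and 4–6 grid units. A displaced
dot moves by a distance drawn uniformly within its annulus, in a uniformly
random direction. The exact per-level probability tables of the original
stimuli are not published; the package default
(`default_distortion_schedule()`) fixes vectors whose expected displacement
increases strictly over L2 < L3 < L4 < L5 < L7, which is the property all
downstream analyses rely on. The schedule lives in data, not code, and can
be replaced from a YAML/JSON file (`read_distortion_schedule()`). Dots
pushed beyond the canvas are reflected at the edge — a deterministic,
order-preserving rule that keeps the nine-point and in-bounds invariants
without resampling bias. Dot order defines polygon connectivity and the
polygon is closed from the last dot back to the first. Color, which the
behavioral task declares category-irrelevant, is not modeled.

## Encoding

`render()` converts a shape to the network's 144-element input: the canvas
is partitioned into a 12 x 12 grid (fixed by the 144-node input layer) and
each cell's activation is the fraction of the cell covered by the filled
polygon, estimated on a 4 x 4 subsample per cell. Nine dots connected in
random order typically produce a self-intersecting outline, so "filled" is
defined by the even-odd rule. Occupancy fractions (rather than a binary
mask) are used so that blurring has something to preserve. A degenerate
(collinear, zero-area) polygon is rejected as an invalid stimulus.

The "Blurry" task reduces the spatial frequency of the stimuli at three
strengths. The simulation analog smooths the occupancy matrix with a
normalized separable box kernel and rescales to maximum 1. Kernel widths are
3, 5 and 7 cells for low/medium/high: box kernels must have odd width to
keep the image centered, and a width-1 kernel would be the identity, so
widths {1,2,3} cannot realize three graded, strictly smoothing levels. With
{3,5,7} the spatial roughness (Laplacian energy) of any encoding strictly
decreases as blur increases, which is the property the tests assert.

## The learner

The network is a 144-144-144 fully connected feedforward auto-associator
with logistic sigmoid hidden and output units. Initial weights are i.i.d.
uniform on [-0.05, 0.05] (configurable); biases start at zero. Training is
online gradient descent on half the squared reconstruction error, target =
input encoding, for category members; non-member trials drive no
associative update but enter the decision-rule calibration below. One epoch
is one pass over the repeat-expanded training manifest in a seeded random
order.

Each member update applies

    w <- w - eta * dE/dw + lambda * w

with learning rate `eta` and decay coefficient `lambda`. The four named
presets (`sim_config()`) fix the study's parameters: typical development
(`td`): eta = 5e-05, lambda = 0, 3 epochs; reduced plasticity
(`asd_reduced_lr`): eta = 2.1e-05; diminished stability (`asd_nwd`):
eta = 5e-05 with lambda = -0.0007; single-epoch variants at eta = 6e-04 and
eta = 0.1. Twenty replicate networks per condition, with one seed stream for
the typical group's initial weights and a separate stream for the atypical
group's, and — the within-subject design — the same initial weights reused
for every training condition of a given replicate.

**Decay convention.** The sign convention of the decay term is not uniquely
determined by its published magnitude, so the package fixes it by the
mechanism it is meant to model: diminished synaptic *stability*, i.e. the
erosion of feedback-driven weight changes. With the update above,
`lambda = -0.0007` shrinks every weight by 0.07% per update, continuously
degrading what training has written into the weights. The opposite
convention (weight inflation) was evaluated and rejected: at these learning
rates inflation acts as a gain amplifier and makes the decay networks *more*
selective than the typical networks at every initial-weight scale tried,
inverting the intended effect. Under erosion the decay networks' post-training
weight norm is smaller than their no-decay counterparts', and their profiles
sit below the typical networks' — the intended pattern.

## The endorsement decision

The behavioral literature reports endorsement rates but not the decision
mechanism, so the rule here is a documented design choice with two parts.

**Familiarity.** At the study's learning rates the absolute reconstruction
error of a stimulus is dominated by the stimulus's own geometry (how much
canvas it covers) rather than by anything the network learned; measured on
the Repeated regimen, the spread of raw member familiarity is more than an
order of magnitude larger than the learning-induced differences between
classes. Familiarity is therefore defined *baseline-corrected*: the
reduction in reconstruction error relative to the same network's initial,
pre-training state (`familiarity(net, x, baseline)`). This isolates the
learned component; an untrained network is exactly equally (un)familiar with
everything.

**Choice.** After training and before the test phase, the rule is calibrated
per network from the training items: the threshold is the midpoint between
the mean member and mean foil familiarity (both stimulus sets were trained
with feedback, so both are available to the learner). `endorse()` is the
deterministic version — endorse iff familiarity reaches the threshold.
Simulated endorsement *rates* use the graded choice rule
`P(endorse) = plogis((familiarity - threshold) / tau)` and report its
expectation over each class's test items, mirroring means over many
stochastic decisions without trial-sampling noise. The sensitivity `tau` is
a fixed property of the decision process, not re-fit per condition: it was
calibrated once so that typical networks under the Repeated regimen endorse
the prototype at a high rate (about 0.95) with low foil endorsement, and is
then held constant (default 0.004 familiarity units) across every learner
variant. This single absolute constant is what allows the learning-rate
manipulation to express itself: the reduced-plasticity networks' familiarity
margins are a fixed fraction of the typical networks' (the ratio of the
learning rates), so any rule that re-normalized per condition would erase
the group difference entirely.

## Simulation design

`build_sim_battery()` constructs one prototype, one training manifest per
regimen and one paired test set from the master seed, and every preset and
replicate reuses this fixed stimulus battery — the analog of running all
networks on a single input set, so condition contrasts reflect learner
parameters rather than stimulus resampling. Replicates differ in initial
weights and presentation order. `run_within_subject_battery()` runs the full
preset-by-regimen grid (the default 4 presets x 4 regimens x 20 replicates
completes in well under a minute on one CPU; profiles are 144 x 144 matrix
operations over at most a few hundred online updates).

`mixture_profile()` forms count-weighted averages of component profiles,
e.g. combining 7 typical-profile with 6 atypical-profile networks
(weights 7/13 and 6/13) into one group-level pattern.

**A known limitation.** The single-epoch 6e-04 variant cannot be made
*depressed* relative to the 3-epoch 5e-05 networks in this implementation:
its cumulative learning (updates x learning rate) is strictly larger, and
endorsement increases monotonically with learning here. The original
simulation environment evidently occupied a regime with strong
non-monotonicities that its published parameters alone do not pin down. The
package therefore asserts the attainable parts of that profile's signature —
foil endorsement at or above the 30% Type II boundary, and a compressed
(saturated) top of the gradient — and documents this divergence rather than
tuning hidden constants to force the remainder.

## Behavioral classification and the synthetic cohort

`classify_profile()` applies the inclusive 30% criterion to the random-class
endorsement proportion; computing from counts or proportions is equivalent,
and the proportion is taken over *answered* random trials (missing trials,
defined behaviorally by the 7-second timeout, are excluded from the
denominator — the denominator convention is configurable at the data level
since the original choice is ambiguous). `apply_exclusions()` drops children
with more than four missing trials in a task (exactly four is retained) and
children whose answered responses strictly alternate member/non-member in
every task they completed; the tolerated number of alternation breaks is a
parameter, default 0. `switch_table()` partitions individuals into stay-I,
stay-II and switch (any adjacent-task label change), with multiple switches
(two or more changes, three or more tasks) reported as a sub-count of the
switchers.

`generate_cohort()` draws each child's latent profile (typical with
probability `p_typical`, default 0.5), evolves it across tasks with per-task
switching probability `p_switch` (default 0.36, the observed two-task
switching rate), and generates each task's 60 trials as independent
Bernoulli endorsements at the latent profile's class means, with i.i.d.
missingness (default 0.02, making more-than-four missing trials rare). The
default class means digitize the qualitative contrast between the two
behavioral profiles — typical (0.90, 0.85, 0.80, 0.70, 0.60, 0.50, 0.10),
atypical (0.35, 0.40, 0.35, 0.35, 0.30, 0.30, 0.45) — and are synthetic
defaults, not measured values. With the default atypical random-class mean
of 0.45, binomial sampling over 30 random trials overlaps the 30% boundary
(about 3% of atypical tasks classify as Type I), which is a realistic amount
of criterion noise; validation tests that require near-perfect label
recovery use a better-separated mean of 0.5. Trials are independent within
a task (no learning drift across the test phase) — a stated simplification,
so closed-loop successes here do not speak to serial-position or fatigue
effects in real data.

`recover_parameters()` closes the loop: `p_typical` is estimated from
first-task label frequencies and `p_switch` from adjacent-task label
disagreement, each with exact binomial confidence intervals. Estimates are
attenuated slightly by classification noise when profile means approach the
boundary; the tests assert this degradation is monotone.

## Reporting

`summarize_groups()` produces group-by-class means with seeded bootstrap
percentile intervals and the Type I minus Type II contrast on pooled member
endorsement (prototype through L7 — deliberately excluding the random class
that defines the grouping). Bootstrap reporting is used throughout instead
of the original study's ANOVA/GLM machinery, which requires the human
sample; effect *directions* are preserved as testable contrasts.
`run_pipeline()` executes either the simulation battery or the
cohort-classification chain end to end, writing tidy CSVs and a JSON
manifest with the seed and config hash so every output is exactly
replayable; an omitted seed is auto-drawn and logged.

## Problem sizes and tolerances

The test suite runs the full battery at the study's scale (20 replicates);
Monte-Carlo stimulus properties use 300–1,500 draws with 3-standard-error
tolerances; cohort recovery uses 1,000 children x 2 tasks against 95%
binomial intervals; gradient correctness is checked against central finite
differences on a 3-3-3 network at 1e-5 relative error. These sizes were
chosen so each property is comfortably resolved by its tolerance.
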