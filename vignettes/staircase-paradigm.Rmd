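---
title: "An adaptive staircase time-estimation paradigm: model, oracle and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive staircase time-estimation paradigm: model, oracle and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timestair)
```

## The paradigm

`timestair` simulates and analyses a time-estimation task used to induce,
confirm and violate performance expectations through feedback alone. On
every trial the responder tries to reproduce a 1-second interval; the
response is classified as correct when it falls inside a *tolerance
window*, initially 990–1100 ms around the target. The window is adapted
trial-wise by a weighted up/down staircase:

* **hard rule** — a miss widens the window by 3 ms, a hit shrinks it by
  12 ms (6 ms at each boundary);
* **easy rule** — a miss widens by 12 ms, a hit shrinks by 3 ms.

A session consists of a 20-trial training block and two 80-trial
experimental blocks. Block 1 always runs the hard rule, driving the rate
of positive feedback down and inducing a negative performance
expectation. In block 2 the *confirmation* condition keeps the hard rule
while the *violation* conditions silently switch to the easy rule; the
two instruction conditions (`violation_inhibiting`,
`violation_enhancing`) are computationally identical to plain violation
and differ only by label, because the instructions they model have no
stated mechanism at the trial level. Training trials and the first trial
of each experimental block are excluded from scoring, and participants
with accuracy below 6% across the three blocks are excluded altogether.

## The staircase's equilibrium

The staircase is a weighted up/down procedure. At hit probability $p$ the
expected change in window width per trial is
$-p\,s + (1-p)\,w$ for shrink step $s$ and widen step $w$, which vanishes
at

$$p^\* = \frac{w}{w + s},$$

i.e. 20% under the hard rule and 80% under the easy rule, *independent of
the responder*. This is the paradigm's central trick: block-1 accuracy is
pinned near 20% for everyone, and the block-2 rule switch moves the
equilibrium to 80% without any change in the responder. Because 80 trials
are too few to reach the new equilibrium from block 1's narrow window,
observed block-2 accuracy under the easy rule reflects the *transient*
(around 50–55% here), not the asymptote.

```{r equilibrium}
equilibrium_hit_rate(rule_hard())
equilibrium_hit_rate(rule_easy())
```

### Conventions for under-specified corners

Several micro-decisions are not dictated by the verbal description of the
procedure; the package fixes them as follows and exposes none of them as
hidden state:

* **Boundary inclusivity.** Correct means inside the *closed* interval
  `[lower, upper]`. This makes the zero-width window a well-defined
  degenerate state (only an exact hit is correct) rather than an
  ill-posed one.
* **Split of the widening step.** Only the hard rule's shrink is
  explicitly described as split over both boundaries ("6 ms at both
  boundaries"); all steps are applied symmetrically, half at each
  boundary, for consistency. Boundaries are real-valued (1.5 ms
  half-steps are not integers).
* **Window collapse.** If a shrink would cross the boundaries, both clamp
  to the window midpoint (width 0). Widening re-opens the window
  symmetrically, so the state never becomes invalid and the midpoint —
  1045 ms for the initial window — is preserved by every update.
* **Window carry-over.** Block 1 starts fresh from 990–1100 ms (training
  is practice, not calibration of the staircase), and block 2 continues
  from block 1's final window: the difficulty switch is implicit, which
  is exactly the manipulation the paradigm relies on. Both choices are
  config switches (`carry_training_into_block1`,
  `carry_block1_into_block2`).
* **Exclusion reading.** "Accuracy below 6% across all three blocks" is
  read as the *mean* of the three block accuracies; the stricter
  every-block-below reading is available via `reading = "all_blocks"`.

## The synthetic responder

No generative model of the human responder comes with the paradigm, so
the package supplies a deliberately simple one
(`participant_params()`): a normal law centred at `mean_ms` with spread
`sd_ms` (scalar-timing noise), truncated to positive times, mixed with a
rare broad "lapse" component (`lapse_rate`, default 0.02, spread
`lapse_spread_ms` = 1000 ms) for off-task responses, plus an optional
linear drift (default 0). Binary correct/incorrect feedback carries no
directional information about timing error, so the responder does not
recalibrate on feedback — a deliberate non-goal.

Defaults are chosen on first principles, not fitted: `mean_ms = 1000`
(the instructed target), `sd_ms = 100` (a Weber fraction of ~0.1 at a 1-s
interval, the standard scalar-timing magnitude), `lapse_rate = 0.02`.
Cohorts can be made heterogeneous by giving `cohort_spec()` intervals
instead of fixed values; the seed hierarchy is master seed → parameter
draws and per-participant child seeds → per-trial stream, so any
participant reruns bit-identically in isolation.

What the generator does **not** emulate: between-participant variance in
strategy or attention (homogeneous cohorts show only binomial spread in
accuracy, noticeably less than real groups), feedback-driven timing
recalibration, sequential dependencies, or any effect of the instruction
manipulations. Passing tests therefore validate the *staircase dynamics
and the analysis pipeline*, not the psychology of real responders.

## The exact forward oracle

Because the window update is deterministic given the feedback, the
distribution of window states after $t$ trials is supported on a small
lattice. `forward_accuracy_trajectory()` propagates the full state
distribution exactly: each state branches into its hit- and miss-updated
children weighted by the closed-form hit probability (truncated-normal
mixture mass inside the window, `hit_probability()`). States are merged
on boundaries rounded to $10^{-6}$ ms, mass below $10^{-12}$ is pruned
(and the pruned total reported; it stays far below $10^{-9}$ in all
shipped uses), and a $10^{6}$-state cap turns pathological configurations
into a loud error rather than a stall. The oracle is the independent
cross-check for the Monte-Carlo simulator — both must agree within
sampling error — and the engine behind calibration.

```{r oracle}
p <- participant_params(1000, 100, lapse_rate = 0)
fwd <- forward_accuracy_trajectory(p, rule_hard(), 500)
mean(tail(fwd$trajectory, 100))   # pinned near the 0.20 equilibrium
fwd$pruned_loss
```

## Calibration

`calibrate_params()` finds responder parameters whose oracle-predicted
block-1 scored accuracy (80 trials, hard rule, first trial unscored)
matches a target. The published block-1 group means (15.7–17.2%) sit
*below* the 20% equilibrium, which an unbiased responder cannot do — the
transient from the wide initial window approaches the equilibrium from
above. Matching them therefore requires a biased responder whose early
hit probability in the 990–1100 ms window is low, with the window slowly
widening towards equilibrium from below.

One target cannot pin down both `mean_ms` and `sd_ms`. The search
bisects the mean (on the branch below the 1045 ms window midpoint, i.e. a
rushing responder) for each spread on a grid, and returns the solution
whose spread is closest to the scalar-timing prior of 100 ms. With the
published pooled block-1 target of about 16.5% this lands near
`mean_ms ≈ 883`, `sd_ms = 100` — a ~12% underproduction bias, which is
large but not implausible for a high-pressure unfamiliar task, and is the
single knob that makes the printed block-1 band reachable at all.

## The replication protocol

`replicate_reference_study()` is the package's end-to-end benchmark:
calibrate once to the published pooled block-1 mean, then simulate 200
replicate cohorts of 28 participants for the violation and the
confirmation condition and report grand mean block-2 accuracies and their
difference. 200 cohorts of 28 keeps the Monte-Carlo standard error of the
grand means below 0.1 percentage points while running in seconds; the
published comparison values are 53.66% (violation), 16.46% (confirmation)
and −37.21 points (their difference). The simulated violation mean lands
a little *above* the published one (≈55%) — consistent with real block-2
behaviour containing sources of miss not in the responder model — and the
confirmation mean a little above as well (≈19.4%, the staircase
equilibrium plus transient, against a published 16.46% that again sits
below equilibrium).

## The statistics pipeline

The analysis mirrors the standard treatment of a 4 × 2 mixed design:

* `summarize_cohort()` — per condition × block mean, sample SD (n − 1)
  and n.
* `mixed_anova()` — the classical split-plot decomposition, computed
  exactly through subject means and difference scores (with two within
  levels this is lossless). For unbalanced groups the time effect tests
  the unweighted mean of group difference-score means — the Type III
  convention of the major commercial packages. Partial eta squared is
  $SS_{effect}/(SS_{effect}+SS_{error})$ throughout. Planned contrasts
  (violation vs confirmation, inhibiting vs enhancing, experiment 1 vs
  experiment 2 as the mean-of-groups difference) are F tests on the
  difference scores with the within-error mean square.
* `posthoc_mean_difference()` / `marginal_mean_difference()` — pairwise
  and repeated-measures marginal mean differences. From a summary table
  alone only `M_diff` is computed; with per-participant data the package
  adds pooled-variance t comparisons with Bonferroni-adjusted p values
  and simultaneous confidence intervals. The family defaults to all
  pairwise comparisons among the groups present (6 for four groups),
  which reproduces the half-widths of the published intervals from the
  published SDs.
* `bonferroni_adjust()`, `manipulation_check_summary()` — the remaining
  conveniences; self-assessment items are pass-through data, never
  simulated.

The published F statistics and effect sizes for the expectation ratings
are *not* reproduction targets: they depend on raw human data that are
not available. The pipeline is instead validated against a brute-force
sums-of-squares oracle on a hand-checkable fixture and against an
independent Type III repeated-measures implementation.

```{r contrasts}
s <- reference_accuracy_summary()
posthoc_mean_difference(s, "confirmation", "violation", "block2")$m_diff
marginal_mean_difference(s, "confirmation", "violation")$m_diff
```

## Numerical and scale choices

Test-suite and benchmark problem sizes are chosen to keep everything at
desk scale while leaving no estimate noise-limited: equilibrium checks
use 2000-trial forward passes (trailing 500 trials) and 10,000
Monte-Carlo participants; oracle-vs-simulation agreement is asserted at
three standard errors with the standard error estimated from the
per-participant spread; the replication benchmark uses 200 × 28
participants per condition. All randomness flows from a single seed
argument; every output file is byte-identical on rerun.

## Known limitations

* The responder model is intentionally minimal; it reproduces the
  *dynamics* of accuracy under the staircase, not individual differences,
  learning, or instruction effects.
* The calibration resolves a one-target/two-parameter indeterminacy by a
  fixed prior on the spread; other (bias, spread) pairs reproduce block 1
  equally well and would shift block-2 transients by a few points.
* The instruction conditions are labels; modelling how instructions
  modulate expectation change would require a mechanism the paradigm
  description does not provide.
* The exact CI machinery behind the published intervals is inferred
  (pooled-variance Bonferroni t), not documented by the source.
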