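# timestair

Simulation and analysis of adaptive staircase time-estimation
experiments — the class of paradigms that induce, confirm or violate
performance expectations purely through trial-wise feedback.

## The problem

In these experiments a participant reproduces a 1-second interval on
every trial and is told only whether the response fell inside a hidden
*tolerance window* (initially 990–1100 ms). The window is adapted by a
weighted up/down staircase: under the **hard** rule a miss widens it by
3 ms and a hit shrinks it by 12 ms; under the **easy** rule the steps
are swapped (widen 12, shrink 3). The long-run hit rate of such a
staircase is

    p* = widen / (widen + shrink)

— 20% under the hard rule, 80% under the easy rule, *regardless of the
responder*. A session is 20 training trials plus two 80-trial blocks:
block 1 is always hard (inducing a negative performance expectation),
and block 2 either stays hard (expectation confirmation) or silently
switches to easy (expectation violation). Researchers who use or extend
this paradigm need to know, before collecting data, what accuracy
trajectories the staircase itself produces. `timestair` gives them:

* the trial-wise engine (`classify_response()`, `apply_update()`,
  `run_block()`),
* synthetic responders — truncated-normal interval reproduction with
  lapses (`participant_params()`, `cohort_spec()`),
* the full four-condition experiment with the standard exclusion rules
  (`run_participant()`, `run_cohort()`, `apply_exclusions()`),
* an **exact Markov forward oracle** for the accuracy dynamics and a
  calibration routine (`forward_accuracy_trajectory()`,
  `calibrate_params()`),
* the matching statistics pipeline: condition × block summaries,
  split-plot (mixed-design) ANOVA with planned contrasts and partial
  eta squared, Bonferroni post hoc mean differences with pooled-t
  confidence intervals (`summarize_cohort()`, `mixed_anova()`,
  `posthoc_mean_difference()`, `marginal_mean_difference()`),
* reproducible file-based runs (`cli_simulate()`, `cli_analyze()`, and
  the `inst/cli/timestair.R` command-line front end).

## Worked example

```r
library(timestair)

# the staircase pins everyone near 20% in block 1 ...
p <- participant_params(mean_ms = 1000, sd_ms = 100, lapse_rate = 0)
fwd <- forward_accuracy_trajectory(p, rule_hard(), 2000)
mean(tail(fwd$trajectory, 500))
#> [1] 0.200024

# ... and the published block-1 accuracies (~16.5%) sit *below* that
# equilibrium, which requires a biased responder:
cal <- calibrate_params(reference_block1_target())
cal
#> <responder: mean 883.281 ms, sd 100 ms, lapse 0.02 (spread 1000 ms), drift 0 ms/trial>
attr(cal, "achieved_accuracy_pct")
#> [1] 16.48967

# oracle-predicted block-2 accuracy after the silent hard -> easy switch:
predict_block_accuracy(cal, "violation")$block2$expected_accuracy
#> [1] 55.35081
predict_block_accuracy(cal, "confirmation")$block2$expected_accuracy
#> [1] 19.42117
```

The violation condition's ~55% is a *transient*: 80 easy-rule trials are
not enough to climb from block 1's narrow window to the 80% equilibrium —
the same reason the published violation groups scored near 50% rather
than 80%, while confirmation groups stayed near the 20% hard equilibrium.

The contrast machinery reproduces the published post hoc mean
differences straight from the published group summary:

```r
s <- reference_accuracy_summary()
posthoc_mean_difference(s, "confirmation", "violation", "block2")$m_diff
#> [1] -37.2
marginal_mean_difference(s, "confirmation", "violation")$m_diff
#> [1] -19.325
```

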