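---
title: "Decision/movement coregulation in the Tokens task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision/movement coregulation in the Tokens task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In a two-phase sensorimotor task, participants watch two "bananas" grow
around a circular track at 60 Hz; on every frame exactly one of them is
extended by 2 degrees, and after 179 frames (2983 ms) one banana is always
strictly longer. Participants press a left or right key to predict the
winner (decision phase) and then tap the same key four more times to move a
caterpillar (movement phase, fixed 3000 ms). Time pressure is applied to
*either* the decision (fast- vs slow-decision blocks) *or* the tapping
(fast- vs slow-tapping blocks, enforced by a snake moving at 85% or 59.5%
of the participant's maximum tapping speed). The question is whether
speeding up one phase spontaneously speeds up the other — the behavioral
signature of embodied decision-making, in which deciding and moving share
neural machinery.

`tokentap` implements the complete analysis chain for this question on
synthetic cohorts with planted condition effects: stimulus generation,
cohort simulation, behavioral endpoints with robust statistics,
drift-diffusion modelling with Bayesian model comparison, and
psychophysical (reverse-correlation) kernels. Because every planted effect
is stored as ground truth, each analysis stage can be validated by
recovery.

## Evidence model and trial types

With `delta` the frame-count lead of a banana and `remaining` frames to
come, the objective success probability treats each remaining frame as an
independent fair coin:

$$P(\text{win}) = P(\delta + 2K - r > 0), \qquad K \sim \mathrm{Bin}(r, 1/2),$$

ties counting as losses. `success_probability()` evaluates this via the
binomial tail; `success_probability_oracle()` enumerates all `2^r`
assignments and serves as the exact oracle in the tests.

Trial difficulty types are defined on the running success probability
`p_w(t)` of the eventual winner:

* **obvious** — `p_w(t) >= 0.6` for all frames after a 30-frame burn-in;
* **misleading** — `p_w(t) <= 0.4` at some frame in the first 90 (the
  winner looks like the loser early on);
* **ambiguous** — `p_w(t)` stays strictly inside (0.3, 0.7) throughout the
  first 90 frames;
* **random** — anything else.

All band edges, the burn-in and the "early" horizon are constants in
`task_design()`. The ambiguous band is deliberately wider than the
obvious/misleading thresholds: requiring `p_w` to stay inside (0.4, 0.6)
for 90 frames describes roughly a 1-in-30,000 coin-flip sequence, which
makes rejection sampling computationally degenerate, while (0.3, 0.7)
corresponds to a lead within about five frames — visually a neck-and-neck
race — and accepts about 7% of draws. Because `p_w` is monotone in the
lead at fixed `remaining`, each band is precompiled into integer lead
thresholds once per design; the classifier on thresholds is property-tested
against the direct probability computation.

Trial lists (`make_trial_list()`) contain exactly 30/30/20/20 percent of
the four types (so the trial count must be a multiple of 10), with winner
sides counterbalanced within type by mirror-imaging every second accepted
sequence. For the `random` type the first draw is accepted unconditionally
— any growth pattern is legal — so only the three structured types are
guaranteed to classify as requested.

## The synthetic cohort: a stated world

The generative agent is deliberately *not* the analysis-side diffusion
model: it integrates the actual frame sequence,

$$X_k = X_{k-1} + \mathrm{gain}\cdot s_k + \varepsilon_k,
  \qquad \varepsilon_k \sim N(0, \sigma),$$

committing when `|X_k|` reaches a condition-specific bound, with the key
press following after a Gaussian motor delay (floor 50 ms). Kernels
computed on data from a plain diffusion (which never sees the frames)
would be flat; integrating the true stimulus is what makes the
reverse-correlation analysis meaningful.

Two generator choices deserve justification:

* **Deadline urgency.** With bounds large enough to produce realistic
  decision durations, many misleading/random sequences never drive the
  accumulator to the bound, which would make 20–50% of trials no-responses
  — an order of magnitude above the few percent seen empirically. Agents
  therefore commit to the currently leading alternative at a forced
  frame, chosen so the motor delay still fits inside the 3000-ms timeout
  (`forced_commit_frame`, computed per condition). This mirrors the
  urgency/collapsing-bound behavior that is standard in Tokens-task
  modelling. The low-level `agent_params()` default disables forcing, so
  the bound-to-infinity limit still yields a no-response.
* **Simple response distributions.** Tap intervals are truncated Normal
  (floor 60 ms) rather than lognormal; anticipation lapses are uniform on
  (0, 140) ms and no-response lapses missing, each at half the lapse
  probability.

The default `cohort_config()` states the simulated world once, at the
scale of the study it emulates: about 60 participants, 2 sessions × 2
conditions × 4 blocks × 40 trials plus 40-trial SRT blocks, and planted
fast-minus-slow effects calibrated so group endpoints land near the
published magnitudes — decision durations around 1030/1680 ms
(fast/slow-decision), tap-interval differences of 16 ms (decision session)
and ~119 ms (movement session), a movement-session decision-duration
difference near −90 ms, and a simple-reaction-time task built as a fixed
180-ms detection latency plus the same motor delay as the main task (the
study does not print its SRT magnitudes, so the detection latency is a
free parameter flagged in the configuration). Accumulator noise 0.6 per
frame and bounds 8.3/15.5 (decision session) and 12.1/13.2 (movement
session) were chosen once by direct calibration and then frozen.

What the generator does *not* emulate: learning and fatigue across blocks,
sequential dependencies, lognormal reaction-time tails, and the full
empirical speed–accuracy landscape — under deadline-forced commitment the
success-probability contrast compresses to roughly 0.70/0.78 versus the
published 0.71/0.86. A green recovery test therefore establishes that the
pipeline detects planted effects of realistic size in realistic noise, not
that the generator reproduces every moment of human data.

## Endpoints and robust statistics

Exclusions follow the published rules, in order of precedence:
no-responses; premature presses; frame-rate violations (≥ 1 Hz off 60 Hz);
and anticipations, defined as a per-trial decision duration (reaction time
minus the participant's mean SRT in the *matching* block) under 150 ms.
SRT trials themselves are dropped when premature or faster than 50 ms. The
matching granularity is participant-and-condition (the movement session has
condition-specific SRT blocks; the decision session has a single snake-free
block) — the source text does not state the granularity, so it is an
explicit, documented choice.

Endpoints per participant × session × condition: decision duration
(mean RT minus matching SRT mean), mean objective success probability at
the response frame (RT mapped to its containing frame by ceiling — the
moment-of-decision convention is not stated in the source, so the frame
containing the key press is used), tap duration, and movement accuracy
(over decision-correct trials). Decision measures use movement-correct
trials only.

The reported "S" statistics in the source are consistent with counts of
participants moving against the group direction, so the exact sign test
(`paired_sign_test()`, S = number of positive differences, exact binomial
two-sided p) is the pipeline default, with the Wilcoxon signed-rank test
(`wilcoxon_signed_rank()`) available via configuration; both are always
computable and neither is guessed to be the original intent.

Correlation robustness repeats Spearman tests after removing bivariate
outliers flagged by a reweighted fast-MCD: raw MCD with subset size
`floor((n+3)/2)` (via `MASS::cov.mcd`), chi-square(2) 0.975 cutoff,
consistency-corrected reweighting, final distances from the reweighted
estimate. Within-subject condition CIs use Cousineau centering with the
Morey `sqrt(C/(C-1))` correction. The Holm step-down adjustment is
implemented directly and cross-checked against `p.adjust`.

## Drift-diffusion modelling

The Wiener first-passage density (noise scale 1, absorbing boundaries
{0, a}, start point fixed at `0.5·a` — no response bias, as the task
demands equal left/right responses) is implemented in C++ using the
standard dual-series representation, switching between the small-time and
large-time expansions by whichever needs fewer terms for absolute error
1e-7. Five percent of responses are treated as outliers, uniform over
(0, max observed RT] and split evenly across boundaries; the likelihood is
the 0.95/0.05 mixture. Reaction times under 150 ms are discarded before
fitting. Correct responses terminate at the upper boundary.

Five candidate models let the threshold `a`, non-decision time `t0`,
and/or drift `v` differ between conditions, parameterized as a
slow-condition intercept plus a fast-condition difference: none, `a`,
`t0`, `a+t0`, `a+t0+v`.

* **MLE path** (`fit_subject_mle()`): bounded multi-start optimization
  (first start from EZ-style moment matching), deterministic under a fixed
  seed; this is the fast default for per-subject fits.
* **Hierarchical path** (`fit_hierarchical()`): subject parameters Normal
  around group means, weakly-informative priors (threshold mean
  `N(2, 2)` truncated above 0.1; drift `N(0, 5)`; non-decision time
  `N(0.4, 1)` truncated at 0; differences centered at 0; group SDs
  Half-Normal(1) — the original analysis relied on its tool's defaults,
  which are not printed, so recovery is tested against these stated
  priors). Sampling is Metropolis-within-Gibbs: joint random-walk subject
  updates with burn-in-only adaptation, conjugate Gibbs group means with
  prior truncation, log-scale random-walk group SDs. The default schedule
  (5000 burn-in, every third of 6000 kept, 2 chains) retains 4000 samples
  per parameter; tests and the acceptance suite run reduced schedules.
  Convergence is summarized by the Gelman-Rubin statistic (< 1.1
  satisfactory); a violating fit is flagged, not discarded.

Model comparison uses `BPIC = Dbar + 2·pD` with `pD = Dbar − D(posterior
mean)`; DIC is reported alongside. Within-subject effect certainty is the
fraction of posterior samples of a difference parameter below zero, with
97% as the conventional existence threshold and the label resolution
limited by the sample count (4000 samples ⇒ "> 99.975%"). Posterior
predictive checks compare observed RT quantiles (correct/error) and
accuracy against simulation intervals.

## Psychophysical kernels

Momentary evidence is summed in sliding windows of 200/300/400/500 ms
(12/18/24/30 frames), moved one frame at a time. A window is indexed by its
*final* frame — the first moment all its evidence has been seen — which
keeps the post-commitment nullity sharp: windows lying fully after
commitment cannot correlate with the choice. Responses are mapped to their
containing frame by ceiling; lag 0 is the window ending at the response
frame. Trials too short for a lag drop out at that lag; lags with fewer
than 10 trials are undefined, and kernels with fewer than 30 trials are
refused (the source states no minima; these are conservative defaults).

Kernel statistics per participant × condition × timespan: the peak is the
maximum correlation between the expected decision onset (minus the median
RT) and the response, ties broken toward the response; the slope is the
OLS slope of the kernel from onset to peak in correlation units per
second; the peak latency is the time from peak to response (the
sensorimotor-delay proxy). Condition comparisons run a Shapiro-Wilk gate
(paired t if not violated, else Wilcoxon signed-rank, with an exact sign
test for degenerate all-equal differences) and Holm correction across the
four timespans per session and measure.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → endpoints → DDM → kernels, persists
every intermediate (`trials.csv`, `srt.csv`, `meta.json`,
`endpoints.csv`, `kernel_stats.csv`, `report.json`), validates its
configuration against unknown keys, and is byte-reproducible under a fixed
seed (participant `i` derives its seed as `seed + i`; chains as
`seed + chain`). A thin command-line front end
(`inst/cli/tokentap.R`) exposes `simulate`, `endpoints`, `kernels`,
`ddm-fit` and `run` subcommands over the same functions.

## Known limitations

* The generator's success-probability contrast is compressed relative to
  the published medians (see above); acceptance rests on planted-effect
  recovery, not on reproducing that contrast.
* At 40 participants, the movement session's paper-magnitude bound effect
  (about −4% of the threshold) moves kernel slopes in the planted
  direction on every timespan but does not survive Holm correction
  (p ≈ 0.07); the original study had 59 participants and larger empirical
  slope differences. The acceptance test asserts direction there and
  significance in the decision session.
* The hierarchical sampler is a general-purpose Metropolis scheme; at
  strongly reduced schedules its Gelman-Rubin values can exceed 1.1 and
  are reported honestly via the `converged` flag.
* Inter-trial variability parameters (sv, st, sz) are intentionally absent
  — the compared model family does not include them — and the response
  bias is fixed at 0.5 rather than estimated.
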