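---
title: "Closed-loop stimulation triggers and the virtual-rat model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop stimulation triggers and the virtual-rat model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clvns)
```

## The paradigm

`clvns` implements the quantitative machinery of closed-loop vagus nerve
stimulation (CLV) paired with an automated isometric pull task. A rat pulls a
handle; the force transducer is sampled every 10 ms; a trial opens when force
reaches 10 g and closes 2 s later; the trial's outcome is its peak force. Two
adaptive criteria are evaluated against the peak forces of the ten preceding
trials of the session:

* the **reward threshold** — the median of the trailing ten peaks, clamped to
  [10, 120] g, fixed at 10 g for a session's first ten trials — gates pellet
  delivery;
* the **stimulation threshold** — an order statistic of the same ten peaks —
  gates a 0.5 s train of vagus nerve stimulation (16 biphasic pulses, 100 µs,
  0.8 mA, 30 Hz) under one of four trigger policies: Top 20% (immediate,
  ~50 ms after the threshold crossing), Delayed Top 20% (same trials,
  delivered at the window end), Bottom 20% (weakest quintile, window end),
  and Top 50% (above the upper median or above 120 g, immediate), plus a
  rehabilitation-only control.

The scientific question the paradigm probes is *timing*: stimulation converts
a decaying synaptic eligibility trace left by a successful movement into
lasting plasticity, so stimulation seconds away from success should do little,
and stimulation within a couple of seconds should do a lot.

## Quantiles as order statistics

"Top quintile of the previous ten trials" is implemented as the 2nd-largest
of the ten buffered peaks, with *exceed* meaning strictly greater; "bottom
quintile" as the 2nd-smallest, with *fail to exceed* meaning less-or-equal;
the Top-50% trigger as the upper median (6th-smallest), strictly exceeded.
With continuous i.i.d. peak forces the new trial and the ten buffered trials
are eleven exchangeable values, so the trigger probabilities are exact
rational numbers: 2/11 for either quintile rule and 5/11 for the median rule
(when the 120 g absolute trigger never binds). Two structural facts follow
with no free parameters:

* **parity** — Top 20% and Bottom 20% deliver the same expected amount of
  stimulation, 2/11 of eligible trials each;
* **pairing ratio** — Top 50% delivers (5/11)/(2/11) = **2.5×** the
  stimulations of Top 20% on the same force stream.

The upper-median convention is deliberate: reading "exceeds the median" with
the interpolated (mean-of-middle-two) median would make the trigger
probability depend on the force distribution (exactly 1/2 for a symmetric
conditional) and the pairing ratio 2.75 rather than the 2.5 the paradigm is
built around. The *reward* threshold, by contrast, keeps the conventional
interpolated median — it is a shaping criterion, not a rank test, and its
clamp to [10, 120] g dominates its behavior.

The reward threshold's interpolation scheme is the package default; no
alternative percentile scheme is offered for the stimulation thresholds
because the rank reading is what makes the closed forms exact.

## Trial detection choices

Tick times are integer milliseconds; the trial window is the *closed*
interval `[init, init + 2000]` ms, so a sample landing exactly on the window
end belongs to the trial. The task description does not say whether a pull
still above threshold when the window closes may immediately open a new
trial; `detect_trials()` requires at least one sub-threshold sample before
re-arming, so one sustained pull is one trial. Windows truncated by the end
of a session are kept and flagged `truncated`. These choices are deterministic
conventions, checked against a brute-force reference scan in the tests.

## The virtual rat

The generator exists to exercise the closed loop end to end and to encode the
timing hypothesis; it is not a biophysical model. Its state is a single
latent **capability** (grams): pull apexes are `capability × exp(σZ)` with
`σ = 0.35` (a continuous, positive, multiplicative-scale family — continuity
is what makes the exchangeability closed forms hold); inter-attempt gaps are
exponential with mean 15 s (~110–130 trials per 30-min session — trial rates
are not reported for the task, so this is a package default); each pull is a
triangular pulse (300 ms rise, 500 ms fall), which makes initiation,
threshold-crossing and peak times available in closed form and renderable as
a 10 ms-sampled trace for the detector to re-derive.

A trained rat has capability 175 g, at which ~85% of pulls exceed 120 g —
the task's proficiency criterion. The cervical contusion multiplies
capability by **0.23** once (the reported 77% loss of volitional strength).
Recovery has two channels, both capped at the pre-injury ceiling:

* every rewarded trial adds `baseline_learning_rate` (0.005 g) — slow,
  policy-independent rehabilitative learning;
* every stimulation adds `gain · exp(−Δt/τ)`, where `Δt` is the delay from
  the nearest antecedent *successful* trial — operationally, the moment force
  first crossed the reward threshold on the most recent rewarded trial — and
  `τ = 5 s`. The exponential is the minimal kernel consistent with the
  qualitative constraints: near-full benefit within ~2 s, negligible benefit
  at 25 s (`exp(−5) ≈ 0.007`), a precision limit on the order of 10 s.

The stimulation gain default (0.20 g per perfectly-timed stimulation) is set
so that all three precisely-timed arms — Top 20%, Delayed Top 20% (kernel
`exp(−~1.8/5) ≈ 0.7` per stimulation), and Top 50% (2.5× the stimulations) —
saturate at the ceiling within the six therapy weeks, reproducing the
reported comparability of those arms, while the Bottom 20% arm (delays of
tens of seconds) stays with the rehabilitation-only control. With `gain = 0`
all arms collapse onto baseline learning, a null the tests exercise.

The timeline mirrors the study arc: two PRE assessment days, injury, two
POST days, six therapy weeks of 2 × 30-min sessions five days per week, with
stimulation disabled in the final week to probe lasting effects. The
threshold buffer resets at every session start, and the two daily sessions
are simulated back-to-back (the ≥2 h gap carries no model content). Each
animal runs on its own derived seed.

What the generator does **not** emulate: within-session fatigue or
motivation drift, autocorrelated pull forces, day-to-day variability in
trial rates, multi-joint kinematics, or any anatomy (tracer counts and motor
maps are *inputs* to the histology arithmetic, never simulated outputs).
Passing tests therefore demonstrate that the controller, thresholds and
analytics are correct and that the timing hypothesis produces the expected
orderings under clean assumptions — not that real sessions look like this.

## The timing statistic

The separation between stimulation and success is summarized per
stimulation as the absolute interval to the peak time of the nearest trial
in the session's top 20% by peak force (mirroring the Top-20% trigger's
definition of "most successful"). Because trigger eligibility uses the
*trailing ten trials* while the reference set is the *whole session*, about
80% of Top-20% stimulations land on reference trials (intervals ~0.2 s) and
the rest sit tens of seconds from one; the mean is therefore dominated by
that minority, and the **median** is the faithful location summary (the
summary reports mean, SD and median; whether the published spread is SD or
SEM across animals is not stated, so both are computable from the pooled
intervals). Under defaults the Top-20% median is ~0.03 s and the Bottom-20%
median ~25–30 s — three orders of magnitude apart, comfortably reproducing
the qualitative separation the delayed-timing comparison relies on.

## Parameter recovery

`fit_clv()` recovers the two latent generator parameters from a simulated
cohort. The injury multiplier is the POST/PRE ratio of mean peak force
(capability enters multiplicatively, so the ratio is a direct estimator).
The eligibility time constant is grid-searched (default grid 3, 4, 5, 6, 8,
12 s): candidate cohorts are re-simulated under common random numbers and
scored by squared error against the observed per-group weekly mean
peak-force curves. The delayed arm's ~1.8 s delivery delay makes its early
recovery slope sensitive to small `τ`; the Bottom-20% arm's tens-of-seconds
delays make its curve sensitive to large `τ`. Problem sizes used throughout
(8 animals per group for the observed cohort, 4 per group and 6 candidate
taus for the reference simulations) keep a full recovery under a few
minutes while leaving the grid's ±1-step neighborhood inside ±20% of the
true value.

## Numerical conventions and edge cases

* Times are milliseconds from session start (doubles in the simulator,
  integer tick times in the detector); forces grams; train parameters in the
  units printed on the hardware (Hz, µs, mA).
* An empty threshold buffer yields `NA` thresholds — no stimulation is
  possible; no policy stimulates before the 11th trial of a session.
* Ties: "exceed" is strict everywhere; "fail to exceed" is `≤`. The
  continuous generator produces no ties almost surely.
* A stimulation with no antecedent successful trial in the session finds no
  eligibility trace and changes nothing.
* Truncated windows, zero-trial weeks, sessions without stimulations, and a
  non-positive reference recovery in `percent_benefit()` are all flagged
  (`truncated`, absent rows, `NA` summaries, a warning) rather than silently
  dropped.

## Known limitations

The capability ceiling makes the precisely-timed arms converge to *complete*
recovery of the pre-injury scale; empirically, recovery is partial. The tier
structure (which arms group together, and how far above the mistimed arms
they sit) is the model's claim; absolute force values are not. Analytics
stop at descriptive group summaries — repeated-measures inference belongs to
a general statistics package, not here. The histology module implements only
the defined arithmetic on extracted counts and areas; combining corticospinal
sub-tract damage into a single weighted total requires fiber-proportion
constants not available to the package and is deliberately left out.
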