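# clvns

Closed-loop vagus nerve stimulation (CLV) trigger policies for the rodent
isometric pull task, with a virtual-rat simulator for exercising the whole
loop without hardware or animals.

## The problem

In CLV-based motor rehabilitation, a brief vagus nerve stimulation train is
delivered the moment a behavioral criterion is met, on the hypothesis that
stimulation converts the decaying synaptic eligibility trace left by a
successful movement into lasting plasticity — so *when* you stimulate matters
more than *how much*. The behavioral rig is an automated isometric pull task:
force sampled every 10 ms, a trial opened at 10 g, a 2 s response window,
peak pull force as the outcome. Two adaptive criteria are evaluated against
the ten preceding trial peaks \(x_{(1)} \le \dots \le x_{(10)}\) of the
session:

* reward threshold: `clamp(median(x), 10 g, 120 g)` (10 g for a session's
  first ten trials);
* stimulation threshold, by policy:
  * **Top 20%** — stimulate iff `peak > x₍₉₎` (2nd-largest), ~50 ms after the
    crossing;
  * **Delayed Top 20%** — same trials, delivered at the window end;
  * **Bottom 20%** — stimulate iff `peak ≤ x₍₂₎`, at the window end;
  * **Top 50%** — stimulate iff `peak > x₍₆₎` (upper median) or `peak >
    120 g`, ~50 ms after the crossing;
  * **Rehab alone** — never.

With i.i.d. continuous forces these rank rules have exact trigger
probabilities (2/11, 2/11, 5/11), giving two structural constants the
package reproduces from scratch: Top 20% / Bottom 20% *parity* and the
Top 50% / Top 20% pairing ratio **(5/11)/(2/11) = 2.5**.

The stimulation train is 16 × 100 µs biphasic pulses at 0.8 mA, 30 Hz — a
0.5 s train measured first-to-last onset.

The package is aimed at engineers and methodologists who need the paradigm's
control logic, its closed-form trigger statistics, and a seeded synthetic
testbed for them: trial detection on force traces, the adaptive thresholds,
all five policies, the train scheduler, session/protocol simulation with an
exponential eligibility-trace kernel (`gain · exp(−Δt/τ)`, τ = 5 s), outcome
analytics, and the quantification arithmetic for motor maps, tracer counts
and lesion sparing.

## Worked example

```r
library(clvns)

# a 30-min closed-loop session for an injured virtual rat under Top 20% CLV
set.seed(1)
res <- simulate_session(rat_state(capability = 40), policy_config("TOP20"))
nrow(res$trials)                 # 112 trials
sum(res$trials$stimulated)       # 19 stimulations (~2/11 of eligible trials)
round(mean(res$trials$rewarded), 2)  # 0.59 success rate

# trigger statistics on a million-trial i.i.d. stream
f50 <- expected_stim_fraction("TOP50", 1e6, seed = 2)$fraction  # 0.4547 (5/11)
f20 <- expected_stim_fraction("TOP20", 1e6, seed = 2)$fraction  # 0.1823 (2/11)
f50 / f20                                                       # 2.495

# full study: 5 groups x 8 animals, PRE / injury / POST / 6 therapy weeks
p <- simulate_protocol(clv_cohort(n_per_group = 8), clv_timeline(), seed = 42)
p
#> <clv_protocol> 40 animals, 5 groups, 287013 trials, seed 42
#>   BOTTOM20       final capability   69.8 g
#>   REHAB_ALONE    final capability   58.7 g
#>   TOP20          final capability  175.0 g
#>   TOP20_DELAYED  final capability  175.0 g
#>   TOP50          final capability  175.0 g
```

The protocol printout is the timing hypothesis in numbers: every
precisely-timed arm (Top 20%, Delayed Top 20%, Top 50%) recovers to the
capability ceiling, while mistimed stimulation (Bottom 20%) stays with the
rehabilitation-only control — despite Bottom 20% receiving as many
stimulations as Top 20%. `weekly_peak_force()`, `group_descriptives()`,
`percent_benefit()` and `pooled_stim_latency()` turn the trial log into the
study's outcome tables, and `fit_clv()` recovers the injury multiplier and
eligibility time constant back from the simulated cohort by grid search.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/clv.R simulate --seed 1 --out run1
Rscript inst/cli/clv.R analyze --log run1/trials.csv --out run1
Rscript inst/cli/clv.R policy-stats --policy TOP50 --n 1000000 --seed 1
```

## Package tour

| Area | Functions |
| --- | --- |
| Trial engine | `force_trace()`, `detect_trials()`, `peak_force()` |
| Adaptive thresholds | `threshold_state()`, `push_trial()`, `reward_threshold()`, `quantile_threshold()` |
| Trigger policies | `policy_config()`, `decide_stimulation()`, `policy_trigger_flags()`, `expected_stim_fraction()` |
| Stim trains | `stim_train_spec()`, `generate_train()`, `train_duration()`, `train_pulse_table()` |
| Virtual rat | `rat_state()`, `behavior_params()`, `sample_attempt()`, `apply_plasticity_update()`, `simulate_session()`, `simulate_protocol()`, `render_force_trace()` |
| Analytics | `weekly_peak_force()`, `stim_to_success_latency()`, `percent_benefit()`, `proficiency_check()`, `group_descriptives()` |
| Histology arithmetic | `icms_map()`, `icms_area_by_category()`, `movement_threshold_stats()`, `normalize_prv_counts()`, `percent_spared()` |
| IO / config | `read_trial_log()`, `write_trial_log()`, `read_force_trace()`, `read_run_config()`, `write_resolved_config()` |
| Parameter recovery | `fit_clv()` |

The methods vignette (`vignettes/clv-methods.Rmd`) documents the model, the
order-statistic conventions, the generator's defaults and what they do and do
not emulate.
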