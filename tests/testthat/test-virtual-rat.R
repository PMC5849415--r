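test_that("attempt apexes scale multiplicatively with capability", {
  params <- behavior_params()
  set.seed(51)
  a1 <- replicate(2000, sample_attempt(rat_state(capability = 100), params)$apex_g)
  set.seed(51)
  a2 <- replicate(2000, sample_attempt(rat_state(capability = 50), params)$apex_g)
  expect_equal(a2, 0.5 * a1)
})

test_that("attempt streams are deterministic under a fixed seed", {
  params <- behavior_params()
  set.seed(52)
  s1 <- sample_attempt_stream(rat_state(), params, 120000)
  set.seed(52)
  s2 <- sample_attempt_stream(rat_state(), params, 120000)
  expect_identical(s1, s2)
})

test_that("empirical mean inter-attempt gap matches the configured mean", {
  params <- behavior_params(mean_intertrial_s = 8)
  rat <- rat_state()
  set.seed(53)
  gaps <- replicate(1e4, sample_attempt(rat, params)$gap_ms) / 1000
  se <- 8 / sqrt(1e4)   # exponential: sd = mean
  expect_lt(abs(mean(gaps) - 8), 3 * se)
})

test_that("the eligibility kernel follows gain * exp(-dt / tau)", {
  rat <- rat_state(capability = 40, tau_s = 5, stim_gain = 1)
  up0 <- apply_plasticity_update(rat, 1000, 1000)
  expect_equal(up0$capability - rat$capability, 1)            # dt = 0
  up1 <- apply_plasticity_update(rat, 6000, 1000)
  expect_equal(up1$capability - rat$capability, exp(-1))      # dt = tau
  up2 <- apply_plasticity_update(rat, 26000, 1000)
  expect_equal(up2$capability - rat$capability, exp(-5))      # dt = 25 s: ~0.0067
})

test_that("plasticity uses the nearest antecedent success and guards the ceiling", {
  rat <- rat_state(capability = 174.5, capability_ceiling = 175, stim_gain = 5)
  up <- apply_plasticity_update(rat, 10000, c(2000, 9000, 12000))
  expect_equal(up$capability, 175)    # capped; the 12 s event (future) ignored
  # nearest antecedent event is the one at 9 s
  rat2 <- rat_state(capability = 40, tau_s = 5, stim_gain = 1)
  up2 <- apply_plasticity_update(rat2, 10000, c(2000, 9000, 12000))
  expect_equal(up2$capability - 40, exp(-1 / 5))
  # no antecedent success: no trace to convert
  up3 <- apply_plasticity_update(rat2, 1000, c(2000, 3000))
  expect_equal(up3$capability, 40)
})

test_that("sessions are deterministic and REHAB_ALONE never stimulates", {
  set.seed(54)
  r1 <- simulate_session(rat_state(capability = 40), policy_config("REHAB_ALONE"))
  set.seed(54)
  r2 <- simulate_session(rat_state(capability = 40), policy_config("REHAB_ALONE"))
  expect_identical(r1$trials, r2$trials)
  expect_equal(sum(r1$trials$stimulated), 0L)
  expect_gt(nrow(r1$trials), 50)   # a 30-min session yields on the order of 100 trials
})

test_that("a long TOP20 session stimulates about 2/11 of eligible trials", {
  set.seed(55)
  # hold capability fixed (no learning) so forces stay i.i.d.
  rat <- rat_state(capability = 40, baseline_learning_rate = 0, stim_gain = 0)
  params <- behavior_params(mean_intertrial_s = 3, session_min = 240)
  res <- simulate_session(rat, policy_config("TOP20"), params)
  elig <- res$trials$trial_index > 10
  frac <- mean(res$trials$stimulated[elig])
  p <- 2 / 11
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / sum(elig)))
})

test_that("detect_trials on the rendered trace recovers the simulated attempts", {
  set.seed(56)
  params <- behavior_params()
  att <- sample_attempt_stream(rat_state(capability = 40), params, 120000)
  att <- att[att$apex_g >= 10, ]
  trace <- render_force_trace(att, 125000)
  got <- detect_trials(trace)
  expect_equal(nrow(got), nrow(att))
  expect_equal(got$peak_force_g, att$apex_g, tolerance = 1e-12)
  # initiation within one sample of the analytic crossing time
  analytic_init <- att$start_ms + att$rise_ms * 10 / att$apex_g
  expect_true(all(abs(got$init_time_ms - analytic_init) <= 20))
})

test_that("the injury multiplier reproduces itself in POST/PRE peak forces", {
  set.seed(57)
  rat <- rat_state(capability = 175, injury_multiplier = 0.23,
                   baseline_learning_rate = 0, stim_gain = 0)
  params <- behavior_params()
  pre <- simulate_session(rat, policy_config("REHAB_ALONE"), params)
  post <- simulate_session(apply_injury(rat), policy_config("REHAB_ALONE"), params)
  ratio <- mean(post$trials$peak_force_g) / mean(pre$trials$peak_force_g)
  expect_equal(ratio, 0.23, tolerance = 0.12)   # one session each; CLT-scale noise
})

test_that("capability stays within (0, ceiling] throughout a stimulated protocol", {
  p <- simulate_protocol(
    clv_cohort(groups = c("TOP20", "BOTTOM20"), n_per_group = 2),
    clv_timeline(pre_days = 1, post_days = 1, therapy_weeks = 1),
    seed = 58
  )
  expect_true(all(p$animals$capability_final > 0))
  expect_true(all(p$animals$capability_final <= p$cohort$rat$capability_ceiling))
})

test_that("zero stimulation gain collapses all policies to baseline learning", {
  rat0 <- rat_state(capability = 40, stim_gain = 0)
  p <- simulate_protocol(
    clv_cohort(groups = c("REHAB_ALONE", "TOP20", "BOTTOM20"), n_per_group = 3,
               rat = rat0),
    clv_timeline(pre_days = 0, post_days = 0, therapy_weeks = 2),
    seed = 59
  )
  fin <- aggregate(capability_final ~ group, p$animals, mean)
  expect_lt(diff(range(fin$capability_final)) / mean(fin$capability_final), 0.02)
})

test_that("with tau -> infinity timing stops mattering (TOP20 ~ BOTTOM20 plasticity)", {
  mk <- function(tau) rat_state(capability = 40, tau_s = tau, stim_gain = 0.2,
                                baseline_learning_rate = 0)
  run <- function(policy, tau, seed) {
    set.seed(seed)
    rat <- mk(tau)
    for (i in 1:6) rat <- simulate_session(rat, policy_config(policy))$rat
    rat$capability - 40
  }
  # large tau: per-stimulation increment ~ gain regardless of delay, and the
  # two policies stimulate the same expected number of trials
  g_top <- run("TOP20", 1e6, 60)
  g_bot <- run("BOTTOM20", 1e6, 61)
  expect_gt(g_bot / g_top, 0.8)
  expect_lt(g_bot / g_top, 1.25)
  # small tau: only near-zero-delay stimulation contributes
  s_top <- run("TOP20", 0.05, 60)
  s_bot <- run("BOTTOM20", 0.05, 61)
  expect_lt(s_bot, 0.01 * s_top)
})

test_that("the final therapy week is stimulation-free", {
  p <- simulate_protocol(
    clv_cohort(groups = "TOP20", n_per_group = 1),
    clv_timeline(pre_days = 0, post_days = 0, therapy_weeks = 2),
    seed = 62
  )
  by_week <- tapply(p$trials$stimulated, p$trials$week, sum)
  expect_gt(by_week[["W1"]], 0)
  expect_equal(by_week[["W2"]], 0L)
})
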