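#' Behavioral generator parameters
#'
#' Parameters of the virtual pull-attempt stream. Defaults emulate a trained
#' rat on the isometric pull task: exponential inter-attempt gaps with a 15 s
#' mean (roughly 110-130 trials per 30-min session), lognormally distributed
#' pulse apexes scaled multiplicatively by the rat's latent capability
#' (`sdlog` 0.35), and a triangular force pulse with a 300 ms rise and 500 ms
#' fall. Two 30-min sessions per day, five days per week.
#'
#' @param mean_intertrial_s Mean inter-attempt gap, seconds.
#' @param peak_sdlog Lognormal spread of pulse apexes around capability.
#' @param rise_ms,fall_ms Pulse rise and fall durations, milliseconds.
#' @param session_min Session duration, minutes.
#' @param sessions_per_day,days_per_week Session schedule.
#' @param init_threshold Trial-initiation force, grams.
#' @param window_ms Trial window, milliseconds.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(mean_intertrial_s = 15, peak_sdlog = 0.35,
                            rise_ms = 300, fall_ms = 500, session_min = 30,
                            sessions_per_day = 2L, days_per_week = 5L,
                            init_threshold = 10, window_ms = 2000) {
  stopifnot(mean_intertrial_s > 0, peak_sdlog > 0, rise_ms > 0, fall_ms > 0,
            session_min > 0, sessions_per_day >= 1L, days_per_week >= 1L,
            init_threshold > 0, window_ms > 0)
  structure(
    list(mean_intertrial_s = mean_intertrial_s, peak_sdlog = peak_sdlog,
         rise_ms = rise_ms, fall_ms = fall_ms, session_min = session_min,
         sessions_per_day = as.integer(sessions_per_day),
         days_per_week = as.integer(days_per_week),
         init_threshold = init_threshold, window_ms = window_ms),
    class = "behavior_params"
  )
}

#' Virtual-rat state
#'
#' Latent state of one simulated subject. `capability` sets the scale of the
#' peak-force distribution (grams); a cervical contusion multiplies it by
#' `injury_multiplier` (default 0.23, emulating the ~77% loss of volitional
#' forelimb strength). Rewarded trials nudge capability up by
#' `baseline_learning_rate`; a stimulation adds `gain * exp(-dt / tau)` where
#' `dt` is the delay from the nearest antecedent successful trial — the
#' exponential stand-in for a synaptic eligibility trace decaying over
#' seconds. Capability is capped at `capability_ceiling`.
#'
#' @param capability Latent strength, grams (default 175; a trained rat at
#'   this scale clears 120 g on ~85% of pulls, the proficiency criterion).
#' @param capability_ceiling Upper bound on capability, grams.
#' @param injury_multiplier Fraction of capability retained after injury.
#' @param baseline_learning_rate Capability gain per rewarded trial, grams.
#' @param tau_s Eligibility-trace time constant, seconds (default 5).
#' @param stim_gain Capability gain per stimulation at zero delay, grams.
#' @return An object of class `rat_state`.
#' @export
rat_state <- function(capability = 175, capability_ceiling = 175,
                      injury_multiplier = 0.23, baseline_learning_rate = 0.005,
                      tau_s = 5, stim_gain = 0.20) {
  stopifnot(capability > 0, capability <= capability_ceiling,
            injury_multiplier > 0, injury_multiplier <= 1,
            baseline_learning_rate >= 0, tau_s > 0, stim_gain >= 0)
  structure(
    list(capability = capability, capability_ceiling = capability_ceiling,
         injury_multiplier = injury_multiplier,
         baseline_learning_rate = baseline_learning_rate,
         plasticity = list(tau_s = tau_s, gain = stim_gain)),
    class = "rat_state"
  )
}

#' @export
print.rat_state <- function(x, ...) {
  cat(sprintf("<rat_state> capability %.1f g (ceiling %.1f), injury x%.2f, tau %g s, gain %g g\n",
              x$capability, x$capability_ceiling, x$injury_multiplier,
              x$plasticity$tau_s, x$plasticity$gain))
  invisible(x)
}

#' Apply the contusion injury to a virtual rat
#'
#' Multiplies latent capability by `injury_multiplier` once.
#'
#' @param rat A [rat_state()].
#' @return The injured `rat_state`.
#' @export
apply_injury <- function(rat) {
  stopifnot(inherits(rat, "rat_state"))
  rat$capability <- rat$capability * rat$injury_multiplier
  rat
}

#' Draw one pull attempt
#'
#' Samples an inter-attempt gap (exponential) and a synthetic force pulse:
#' a linear rise to a capability-scaled lognormal apex followed by a linear
#' fall. Uses the current RNG stream.
#'
#' @param rat A [rat_state()].
#' @param params A [behavior_params()].
#' @return A list with `gap_ms`, `apex_g`, `rise_ms`, `fall_ms`.
#' @export
sample_attempt <- function(rat, params) {
  stopifnot(inherits(rat, "rat_state"), inherits(params, "behavior_params"))
  list(gap_ms = stats::rexp(1L, rate = 1 / (params$mean_intertrial_s * 1000)),
       apex_g = rat$capability * exp(stats::rnorm(1L, 0, params$peak_sdlog)),
       rise_ms = params$rise_ms, fall_ms = params$fall_ms)
}

#' Eligibility-trace plasticity update for one stimulation
#'
#' Increments capability by `gain * exp(-dt / tau)` where `dt` is the delay
#' (seconds) between the stimulation and the nearest antecedent successful
#' trial. Events after `stim_time_ms` are ignored; with no antecedent success
#' there is no eligibility trace to convert and capability is unchanged.
#' Capability is capped at the ceiling.
#'
#' @param rat A [rat_state()].
#' @param stim_time_ms Stimulation time, milliseconds.
#' @param success_times_ms Times of recent successful trials, milliseconds.
#' @param tau_s,gain Kernel parameters; default to the rat's own.
#' @return The updated `rat_state`.
#' @export
apply_plasticity_update <- function(rat, stim_time_ms, success_times_ms,
                                    tau_s = rat$plasticity$tau_s,
                                    gain = rat$plasticity$gain) {
  stopifnot(inherits(rat, "rat_state"), tau_s > 0, gain >= 0)
  ev <- success_times_ms[!is.na(success_times_ms) & success_times_ms <= stim_time_ms]
  if (length(ev) == 0L) return(rat)
  dt_s <- (stim_time_ms - max(ev)) / 1000
  if (dt_s < 0) stop("negative stimulation-to-success delay")
  rat$capability <- min(rat$capability + gain * exp(-dt_s / tau_s),
                        rat$capability_ceiling)
  rat
}

#' Simulate one closed-loop training session
#'
#' Runs the full loop at trial resolution: attempts are drawn from the rat's
#' generative model; each supra-threshold attempt becomes a trial with
#' analytic initiation, threshold-crossing and peak times computed from the
#' triangular pulse shape; the reward threshold, trailing buffer and
#' stimulation decision are updated exactly as the controller would on the
#' equivalent force trace (see [render_force_trace()] for the trace view).
#' Rewarded trials deposit an eligibility event at the moment the force first
#' exceeds the reward threshold; stimulations convert the nearest antecedent
#' event into a capability increment via [apply_plasticity_update()].
#'
#' @param rat A [rat_state()]; returned updated.
#' @param config A [policy_config()].
#' @param params A [behavior_params()].
#' @param animal_id,group,week,session Metadata stamped on the log rows.
#' @return A list with `trials` (trial-log data frame) and `rat` (updated
#'   state).
#' @export
simulate_session <- function(rat, config, params = behavior_params(),
                             animal_id = "r1", group = config$policy,
                             week = "W1", session = 1L) {
  stopifnot(inherits(rat, "rat_state"), inherits(config, "policy_config"),
            inherits(params, "behavior_params"))
  session_ms <- params$session_min * 60 * 1000
  state <- threshold_state()
  cap_est <- max(8L, ceiling(session_ms / (params$mean_intertrial_s * 1000)) * 2L)
  init_t <- numeric(cap_est); pk <- numeric(cap_est); pk_t <- numeric(cap_est)
  r_thr_v <- numeric(cap_est); s_thr_v <- numeric(cap_est)
  rew <- logical(cap_est); stim <- logical(cap_est); stim_t <- numeric(cap_est)
  n <- 0L
  success_times <- numeric(0)
  t <- 0
  rise <- params$rise_ms; fall <- params$fall_ms
  repeat {
    att <- sample_attempt(rat, params)
    s <- t + att$gap_ms
    if (s > session_ms) break
    apex <- att$apex_g
    attempt_end <- s + rise + fall
    if (apex < params$init_threshold) { t <- attempt_end; next }
    init_time <- s + rise * params$init_threshold / apex
    peak_time <- s + rise
    w_end <- init_time + params$window_ms

    r_thr <- reward_threshold(state)
    rewarded <- apex > r_thr
    reward_cross <- if (rewarded) s + rise * r_thr / apex else NA_real_

    # stimulation threshold + first crossing time under this policy
    s_thr <- switch(config$policy,
      REHAB_ALONE = NA_real_,
      TOP20 = ,
      TOP20_DELAYED = quantile_threshold(state$buffer, "top_quintile"),
      BOTTOM20 = quantile_threshold(state$buffer, "bottom_quintile"),
      TOP50 = min(quantile_threshold(state$buffer, "median"), config$absolute_cap,
                  na.rm = FALSE)
    )
    crossing <- if (!is.na(s_thr) && apex > s_thr) s + rise * max(s_thr, 0) / apex
                else NA_real_
    dec <- decide_stimulation(
      config, list(init_time_ms = init_time, peak_force_g = apex),
      state, crossing
    )

    # learning: baseline on rewarded trials, eligibility-trace kernel on stim
    if (rewarded) {
      rat$capability <- min(rat$capability + rat$baseline_learning_rate,
                            rat$capability_ceiling)
      success_times <- c(success_times, reward_cross)
      if (length(success_times) > 20L) {
        success_times <- success_times[-seq_len(length(success_times) - 20L)]
      }
    }
    if (dec$stimulate) {
      rat <- apply_plasticity_update(rat, dec$stim_time_ms, success_times)
    }

    n <- n + 1L
    init_t[n] <- init_time; pk[n] <- apex; pk_t[n] <- peak_time
    r_thr_v[n] <- r_thr; s_thr_v[n] <- if (is.na(s_thr)) NA_real_ else s_thr
    rew[n] <- rewarded; stim[n] <- dec$stimulate
    stim_t[n] <- if (dec$stimulate) dec$stim_time_ms else NA_real_
    state <- push_trial(state, apex)
    t <- max(w_end, attempt_end)
  }
  idx <- seq_len(n)
  trials <- data.frame(
    animal_id = animal_id, group = group, week = week, session = session,
    trial_index = idx,
    init_time_ms = init_t[idx], peak_force_g = pk[idx], peak_time_ms = pk_t[idx],
    reward_threshold_g = r_thr_v[idx], stim_threshold_g = s_thr_v[idx],
    rewarded = rew[idx], stimulated = stim[idx], stim_time_ms = stim_t[idx],
    stringsAsFactors = FALSE
  )
  list(trials = trials, rat = rat)
}

#' Render an attempt stream as a sampled force trace
#'
#' Produces the force-transducer view of a stream of triangular pull attempts
#' (as drawn by [sample_attempt()]): each attempt rises linearly from 0 to its
#' apex and falls back to 0, sampled on the acquisition grid. Attempt starts
#' are snapped to the grid so pulse apexes fall exactly on a sample. Used to
#' check that [detect_trials()] on the rendered trace recovers the simulated
#' trials.
#'
#' @param attempts Data frame with columns `start_ms`, `apex_g`, `rise_ms`,
#'   `fall_ms` (non-overlapping attempts).
#' @param duration_ms Trace duration, milliseconds.
#' @param sample_period_ms Sampling period, milliseconds (default 10).
#' @return A [force_trace()].
#' @export
render_force_trace <- function(attempts, duration_ms, sample_period_ms = 10) {
  n <- floor(duration_ms / sample_period_ms) + 1L
  f <- numeric(n)
  t_grid <- (seq_len(n) - 1L) * sample_period_ms
  for (i in seq_len(nrow(attempts))) {
    s <- round(attempts$start_ms[i] / sample_period_ms) * sample_period_ms
    apex <- attempts$apex_g[i]
    rise <- attempts$rise_ms[i]; fall <- attempts$fall_ms[i]
    lo <- which(t_grid >= s & t_grid <= s + rise + fall)
    if (length(lo) == 0L) next
    tt <- t_grid[lo]
    shape <- ifelse(tt <= s + rise,
                    apex * (tt - s) / rise,
                    apex * pmax(0, 1 - (tt - s - rise) / fall))
    f[lo] <- pmax(f[lo], shape)
  }
  force_trace(f, sample_period_ms = sample_period_ms)
}

#' Draw a raw attempt stream (no closed loop)
#'
#' Convenience generator for trace-level tests: sequential non-overlapping
#' attempts over a fixed duration, using the current RNG stream.
#'
#' @inheritParams simulate_session
#' @param duration_ms Stream duration, milliseconds.
#' @return Data frame `start_ms`, `apex_g`, `rise_ms`, `fall_ms`.
#' @export
sample_attempt_stream <- function(rat, params, duration_ms) {
  t <- 0
  start <- numeric(0); apex <- numeric(0)
  repeat {
    att <- sample_attempt(rat, params)
    s <- t + att$gap_ms
    if (s > duration_ms) break
    start <- c(start, s); apex <- c(apex, att$apex_g)
    attempt_end <- s + att$rise_ms + att$fall_ms
    if (att$apex_g >= params$init_threshold) {
      w_end <- s + att$rise_ms * params$init_threshold / att$apex_g + params$window_ms
      t <- max(attempt_end, w_end)
    } else {
      t <- attempt_end
    }
  }
  data.frame(start_ms = start, apex_g = apex,
             rise_ms = params$rise_ms, fall_ms = params$fall_ms)
}
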