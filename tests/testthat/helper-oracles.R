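# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain sample-by-sample scans and
# naive order-statistic lookups.

# Brute-force trial scan: walk the samples, open a closed 2 s window at each
# eligible threshold crossing, take the max inside it, require one sub-
# threshold sample before re-arming.
oracle_detect <- function(forces, period_ms = 10, thr = 10, window_ms = 2000) {
  times <- (seq_along(forces) - 1) * period_ms
  res <- list()
  i <- 1
  need_rearm <- FALSE
  while (i <= length(forces)) {
    if (need_rearm) {
      if (forces[i] < thr) need_rearm <- FALSE
      i <- i + 1
      next
    }
    if (forces[i] >= thr) {
      in_win <- which(times >= times[i] & times <= times[i] + window_ms)
      seg <- forces[in_win]
      res[[length(res) + 1]] <- list(
        init = times[i],
        peak = max(seg),
        peak_t = times[in_win[which.max(seg)]],
        truncated = times[i] + window_ms > times[length(times)]
      )
      i <- in_win[length(in_win)] + 1
      need_rearm <- TRUE
    } else {
      i <- i + 1
    }
  }
  res
}

# naive order-statistic thresholds of a 10-value buffer
oracle_top_quintile <- function(b) sort(b, decreasing = TRUE)[2]
oracle_bottom_quintile <- function(b) sort(b)[2]
oracle_upper_median <- function(b) sort(b)[ceiling((length(b) + 1) / 2)]

# random piecewise force trace: a few triangular pulses on a zero baseline
random_pulse_trace <- function(n_pulses = sample(1:5, 1), len_s = 30) {
  n <- len_s * 100
  f <- numeric(n)
  for (k in seq_len(n_pulses)) {
    start <- sample(seq_len(n - 120), 1)
    rise <- sample(5:40, 1)
    fall <- sample(5:60, 1)
    apex <- runif(1, 1, 150)
    idx <- start:min(n, start + rise + fall)
    tt <- seq_along(idx) - 1
    shape <- ifelse(tt <= rise, apex * tt / rise,
                    pmax(0, apex * (1 - (tt - rise) / fall)))
    f[idx] <- pmax(f[idx], shape)
  }
  f
}

# small standard trial-log fixture builder
make_log <- function(peaks, week = "W1", animal = "a1", group = "TOP20",
                     session = 1, rewarded = NULL, stimulated = NULL,
                     stim_time = NULL, gap_ms = 20000) {
  n <- length(peaks)
  init <- (seq_len(n) - 1) * gap_ms
  data.frame(
    animal_id = animal, group = group, week = week, session = session,
    trial_index = seq_len(n),
    init_time_ms = init, peak_force_g = peaks, peak_time_ms = init + 300,
    reward_threshold_g = 10, stim_threshold_g = NA_real_,
    rewarded = if (is.null(rewarded)) peaks > 10 else rewarded,
    stimulated = if (is.null(stimulated)) rep(FALSE, n) else stimulated,
    stim_time_ms = if (is.null(stim_time)) rep(NA_real_, n) else stim_time,
    stringsAsFactors = FALSE
  )
}
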