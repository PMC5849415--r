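#' CLV trigger-policy configuration
#'
#' The five study arms. `REHAB_ALONE` never stimulates. `TOP20` stimulates
#' ~50 ms after the pull first exceeds the top-quintile threshold of the ten
#' antecedent trials; `TOP20_DELAYED` uses the same trigger condition but
#' delivers at the end of the 2 s trial window; `BOTTOM20` stimulates at the
#' window end on trials failing to exceed the bottom-quintile threshold;
#' `TOP50` stimulates ~50 ms after the pull exceeds the upper-median threshold
#' or the 120 g absolute cap. No policy stimulates during a session's first
#' ten trials (the trailing buffer is still filling) or when `stim_enabled`
#' is `FALSE` (the final therapy week, stimulation-off by design).
#'
#' @param policy One of `"REHAB_ALONE"`, `"TOP20"`, `"TOP20_DELAYED"`,
#'   `"BOTTOM20"`, `"TOP50"`.
#' @param immediate_latency_ms Trigger-to-delivery latency for the immediate
#'   policies, milliseconds (default 50).
#' @param window_ms Trial window, milliseconds (default 2000).
#' @param absolute_cap Absolute trigger force for `TOP50`, grams (default 120).
#' @param stim_enabled Master enable; set `FALSE` for the stimulation-off week.
#' @return An object of class `policy_config`.
#' @examples
#' policy_config("TOP20")
#' @export
policy_config <- function(policy = c("REHAB_ALONE", "TOP20", "TOP20_DELAYED",
                                     "BOTTOM20", "TOP50"),
                          immediate_latency_ms = 50, window_ms = 2000,
                          absolute_cap = 120, stim_enabled = TRUE) {
  policy <- match.arg(policy)
  stopifnot(immediate_latency_ms >= 0, immediate_latency_ms < window_ms,
            window_ms > 0, absolute_cap > 0, is.logical(stim_enabled))
  structure(
    list(policy = policy, immediate_latency_ms = immediate_latency_ms,
         window_ms = window_ms, absolute_cap = absolute_cap,
         stim_enabled = isTRUE(stim_enabled)),
    class = "policy_config"
  )
}

#' @export
print.policy_config <- function(x, ...) {
  cat(sprintf("<policy_config> %s (latency %g ms, window %g ms, cap %g g, stim %s)\n",
              x$policy, x$immediate_latency_ms, x$window_ms, x$absolute_cap,
              if (x$stim_enabled) "enabled" else "disabled"))
  invisible(x)
}

#' Per-trial stimulation decision
#'
#' Applies a trigger policy to one completed trial given the antecedent
#' threshold state. `crossing_time_ms` is the first time the force strictly
#' exceeded the policy's stimulation threshold (absent if it never did); the
#' immediate policies deliver at `crossing_time_ms + immediate_latency_ms`,
#' the window-end policies at `init_time_ms + window_ms`.
#'
#' @param config A [policy_config()].
#' @param trial A list or one-row data frame with at least `init_time_ms` and
#'   `peak_force_g`.
#' @param state The [threshold_state()] reflecting only antecedent trials.
#' @param crossing_time_ms First threshold-crossing time (ms), or `NA`.
#' @return A list with `stimulate` (flag), `stim_time_ms` (or `NA`) and
#'   `threshold` (the triggering threshold in grams, or `NA`).
#' @export
decide_stimulation <- function(config, trial, state, crossing_time_ms = NA_real_) {
  stopifnot(inherits(config, "policy_config"), inherits(state, "threshold_state"))
  no <- list(stimulate = FALSE, stim_time_ms = NA_real_, threshold = NA_real_)
  if (!config$stim_enabled || config$policy == "REHAB_ALONE") return(no)
  if (state$trials_seen < state$capacity) return(no)

  peak <- trial$peak_force_g
  init <- trial$init_time_ms
  window_end <- init + config$window_ms

  if (config$policy %in% c("TOP20", "TOP20_DELAYED")) {
    thr <- quantile_threshold(state$buffer, "top_quintile")
    if (is.na(thr) || !(peak > thr)) return(no)
    if (config$policy == "TOP20") {
      if (is.na(crossing_time_ms)) {
        stop("internal inconsistency: peak exceeds threshold but crossing time is absent")
      }
      return(list(stimulate = TRUE,
                  stim_time_ms = crossing_time_ms + config$immediate_latency_ms,
                  threshold = thr))
    }
    return(list(stimulate = TRUE, stim_time_ms = window_end, threshold = thr))
  }

  if (config$policy == "BOTTOM20") {
    thr <- quantile_threshold(state$buffer, "bottom_quintile")
    if (is.na(thr) || peak > thr) return(no)
    return(list(stimulate = TRUE, stim_time_ms = window_end, threshold = thr))
  }

  # TOP50: exceed the upper-median of the previous 10 trials, or the 120 g cap
  thr <- quantile_threshold(state$buffer, "median")
  eff <- min(thr, config$absolute_cap, na.rm = TRUE)
  if (!(peak > eff)) return(no)
  if (is.na(crossing_time_ms)) {
    stop("internal inconsistency: peak exceeds threshold but crossing time is absent")
  }
  list(stimulate = TRUE,
       stim_time_ms = crossing_time_ms + config$immediate_latency_ms,
       threshold = eff)
}

#' Vectorized trigger flags for an i.i.d. peak-force stream
#'
#' Applies a policy's trigger condition along a single stream of peak forces,
#' using for trial `i` the buffer of forces `i-10 .. i-1`. Trials without a
#' full ten-trial buffer get `NA` (no stimulation possible). With continuous
#' forces and no ties this reduces to rank conditions on eleven exchangeable
#' values and is used for large Monte-Carlo policy statistics; agreement with
#' [decide_stimulation()] trial by trial is part of the test suite.
#'
#' @param peaks Numeric vector of peak forces.
#' @param policy Policy label as in [policy_config()].
#' @param absolute_cap Absolute cap used by `TOP50` (default 120 g).
#' @return Logical vector, `NA` where the trailing buffer is incomplete.
#' @export
policy_trigger_flags <- function(peaks, policy, absolute_cap = 120) {
  n <- length(peaks)
  out <- rep(NA, n)
  if (n <= 10L) return(out)
  if (policy == "REHAB_ALONE") {
    out[11:n] <- FALSE
    return(out)
  }
  w <- stats::embed(peaks, 11L)           # row i: peaks[i+10], peaks[i+9], ..., peaks[i]
  cur <- w[, 1L]
  buf <- w[, -1L, drop = FALSE]
  k <- rowSums(buf < cur)                 # strict exceedances among the previous 10
  kgt <- rowSums(buf > cur)
  flag <- switch(policy,
    TOP20 = ,
    TOP20_DELAYED = kgt <= 1L,            # peak > 2nd-largest of buffer
    BOTTOM20 = k <= 1L,                   # peak <= 2nd-smallest of buffer
    TOP50 = kgt <= 4L | cur > absolute_cap,  # peak > 6th-smallest, or > cap
    stop("unknown policy: ", policy)
  )
  out[11:n] <- flag
  out
}

#' Monte-Carlo stimulated fraction of a policy
#'
#' Draws a long i.i.d. continuous peak-force stream, applies the policy's
#' trigger condition with the trailing ten-trial buffer, and returns the
#' fraction of stimulated trials (the first ten, which have no full buffer,
#' are excluded). Under exchangeability the closed forms are 2/11 for the
#' quintile policies and 5/11 for the median policy when the absolute cap
#' never binds.
#'
#' @param policy Policy label.
#' @param n Number of trials to simulate.
#' @param seed RNG seed.
#' @param force_min,force_max Bounds of the uniform force distribution used
#'   for the stream (defaults keep forces strictly below the 120 g cap).
#' @return A list with `fraction`, `n_eligible`, `n_stim` and the binomial
#'   standard error `se`.
#' @examples
#' expected_stim_fraction("TOP20", n = 2e4, seed = 1)$fraction  # ~ 2/11
#' @export
expected_stim_fraction <- function(policy, n, seed = 1L,
                                   force_min = 10, force_max = 119) {
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  x <- stats::runif(n, force_min, force_max)
  flags <- policy_trigger_flags(x, policy)
  elig <- !is.na(flags)
  p <- if (any(elig)) mean(flags[elig]) else 0
  list(fraction = p, n_eligible = sum(elig), n_stim = sum(flags[elig]),
       se = sqrt(p * (1 - p) / max(1L, sum(elig))))
}
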