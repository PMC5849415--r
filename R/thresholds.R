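#' Trailing-trial threshold state
#'
#' Both the reward threshold and the stimulation thresholds are computed from
#' the peak forces of the ten antecedent trials of the current session. The
#' state holds that trailing FIFO buffer plus the session trial count; it is
#' reset at the start of every session.
#'
#' @param reward_min Lower clamp on the reward threshold, grams (default 10).
#' @param reward_max Upper clamp on the reward threshold, grams (default 120).
#' @param capacity Buffer capacity in trials (default 10).
#' @return An object of class `threshold_state`.
#' @examples
#' st <- threshold_state()
#' st <- push_trial(st, 50)
#' reward_threshold(st)
#' @export
threshold_state <- function(reward_min = 10, reward_max = 120, capacity = 10L) {
  stopifnot(reward_min <= reward_max, capacity >= 1L)
  structure(
    list(buffer = numeric(0), trials_seen = 0L,
         reward_min = reward_min, reward_max = reward_max,
         capacity = as.integer(capacity)),
    class = "threshold_state"
  )
}

#' @export
print.threshold_state <- function(x, ...) {
  cat(sprintf("<threshold_state> %d trial(s) seen, buffer [%s], reward threshold %g g\n",
              x$trials_seen, paste(signif(x$buffer, 4), collapse = ", "),
              reward_threshold(x)))
  invisible(x)
}

#' Record a completed trial in the threshold state
#'
#' Appends the trial's peak force to the trailing buffer (FIFO, oldest value
#' evicted at capacity) and increments the session trial count.
#'
#' @param state A [threshold_state()].
#' @param peak Peak force of the completed trial, grams.
#' @return The updated `threshold_state`.
#' @export
push_trial <- function(state, peak) {
  stopifnot(inherits(state, "threshold_state"), peak >= 0)
  buf <- c(state$buffer, peak)
  if (length(buf) > state$capacity) buf <- buf[-1L]
  state$buffer <- buf
  state$trials_seen <- state$trials_seen + 1L
  state
}

# median as mean of the two middle order statistics (even buffer)
.mid_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else mean(s[c(n %/% 2L, n %/% 2L + 1L)])
}

#' Adaptively scaled reward threshold
#'
#' The pellet-reward criterion: fixed at `reward_min` (10 g) for the first ten
#' trials of a session, then the median peak force of the ten preceding
#' trials, clamped to `[reward_min, reward_max]` (10-120 g). The median of the
#' ten-trial buffer is the mean of its 5th and 6th order statistics.
#'
#' @param state A [threshold_state()].
#' @return Reward threshold in grams.
#' @export
reward_threshold <- function(state) {
  stopifnot(inherits(state, "threshold_state"))
  if (state$trials_seen < state$capacity) return(state$reward_min)
  min(max(.mid_median(state$buffer), state$reward_min), state$reward_max)
}

#' Order-statistic stimulation threshold of the trailing buffer
#'
#' Stimulation thresholds are plain order statistics of the ten antecedent
#' peak forces, with no clamping:
#' \describe{
#'   \item{`top_quintile`}{the 2nd-largest value; a pull "exceeds the top
#'     quintile" when it is strictly greater, i.e. it would rank in the top
#'     two of the eleven forces formed with the buffer.}
#'   \item{`bottom_quintile`}{the 2nd-smallest value; a pull "fails to exceed
#'     the bottom quintile" when it is less than or equal to it.}
#'   \item{`median`}{the upper median (6th-smallest of ten); a pull "exceeds
#'     the median" when strictly greater, i.e. it would rank in the top five
#'     of eleven. With continuous i.i.d. forces this makes the exceedance
#'     probabilities exactly 2/11 (quintile rules) and 5/11 (median rule),
#'     hence the 2.5 pairing ratio between the Top-50% and Top-20% policies.}
#' }
#'
#' @param buffer Numeric vector of antecedent peak forces (grams); normally
#'   length 10. An empty buffer yields `NA` (no stimulation possible).
#' @param mode One of `"top_quintile"`, `"bottom_quintile"`, `"median"`.
#' @return Threshold in grams, or `NA_real_` for an empty buffer.
#' @examples
#' quantile_threshold(10 * 1:10, "top_quintile")    # 90
#' quantile_threshold(10 * 1:10, "bottom_quintile") # 20
#' quantile_threshold(10 * 1:10, "median")          # 60
#' @export
quantile_threshold <- function(buffer,
                               mode = c("top_quintile", "bottom_quintile", "median")) {
  mode <- mode[[1L]]
  n <- length(buffer)
  if (n == 0L) return(NA_real_)
  s <- sort(as.numeric(buffer))
  switch(mode,
    top_quintile = if (n >= 2L) s[n - 1L] else s[n],
    bottom_quintile = if (n >= 2L) s[2L] else s[1L],
    median = s[max(1L, ceiling((n + 1L) / 2))],
    stop("unknown mode: ", mode)
  )
}
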