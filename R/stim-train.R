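#' Stimulation-train specification
#'
#' The vagus-nerve stimulation train used throughout: 16 biphasic pulses,
#' 100 microseconds per phase, 0.8 mA, delivered at 30 Hz, i.e. a 0.5 s train
#' measured first-to-last pulse onset.
#'
#' @param n_pulses Number of pulses (default 16).
#' @param rate_hz Pulse rate in Hz (default 30).
#' @param pulse_width_us Pulse width in microseconds (default 100).
#' @param amplitude_ma Current amplitude in mA (default 0.8).
#' @param biphasic Biphasic pulses flag (default `TRUE`).
#' @return An object of class `stim_train_spec`.
#' @examples
#' train_duration(stim_train_spec())  # 0.5 s
#' @export
stim_train_spec <- function(n_pulses = 16L, rate_hz = 30, pulse_width_us = 100,
                            amplitude_ma = 0.8, biphasic = TRUE) {
  stopifnot(n_pulses >= 1L, rate_hz > 0, pulse_width_us > 0, amplitude_ma > 0)
  structure(
    list(n_pulses = as.integer(n_pulses), rate_hz = rate_hz,
         pulse_width_us = pulse_width_us, amplitude_ma = amplitude_ma,
         biphasic = isTRUE(biphasic)),
    class = "stim_train_spec"
  )
}

#' @export
print.stim_train_spec <- function(x, ...) {
  cat(sprintf("<stim_train_spec> %d x %g us %g mA %s pulses @ %g Hz (%.3g s train)\n",
              x$n_pulses, x$pulse_width_us, x$amplitude_ma,
              if (x$biphasic) "biphasic" else "monophasic",
              x$rate_hz, train_duration(x)))
  invisible(x)
}

#' Pulse onset times of a stimulation train
#'
#' Pulse `k` (zero-based) fires at `onset_s + k / rate_hz`.
#'
#' @param spec A [stim_train_spec()].
#' @param onset_s Train onset time in seconds (default 0).
#' @return Numeric vector of pulse onset times (seconds), length `n_pulses`.
#' @export
generate_train <- function(spec, onset_s = 0) {
  stopifnot(inherits(spec, "stim_train_spec"))
  onset_s + (seq_len(spec$n_pulses) - 1L) / spec$rate_hz
}

#' Train duration (first-to-last pulse onset)
#'
#' `(n_pulses - 1) / rate_hz`; 0.5 s for the default 16-pulse 30 Hz train.
#'
#' @param spec A [stim_train_spec()].
#' @return Duration in seconds.
#' @export
train_duration <- function(spec) {
  stopifnot(inherits(spec, "stim_train_spec"))
  (spec$n_pulses - 1L) / spec$rate_hz
}

#' Export stimulation trains as a flat pulse table
#'
#' @param onsets_ms Numeric vector of train onset times (ms), one per
#'   stimulation.
#' @param spec A [stim_train_spec()].
#' @return Data frame `stim_index, pulse_index, onset_ms, amplitude_ma,
#'   width_us`, one row per pulse.
#' @export
train_pulse_table <- function(onsets_ms, spec = stim_train_spec()) {
  stopifnot(inherits(spec, "stim_train_spec"))
  if (length(onsets_ms) == 0L) {
    return(data.frame(stim_index = integer(0), pulse_index = integer(0),
                      onset_ms = numeric(0), amplitude_ma = numeric(0),
                      width_us = numeric(0)))
  }
  rel_ms <- generate_train(spec, 0) * 1000
  data.frame(
    stim_index = rep(seq_along(onsets_ms), each = spec$n_pulses),
    pulse_index = rep(seq_len(spec$n_pulses) - 1L, times = length(onsets_ms)),
    onset_ms = rep(onsets_ms, each = spec$n_pulses) + rep(rel_ms, times = length(onsets_ms)),
    amplitude_ma = spec$amplitude_ma,
    width_us = spec$pulse_width_us
  )
}
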