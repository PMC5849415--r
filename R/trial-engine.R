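#' Construct a force trace
#'
#' A force trace is the raw output of the isometric pull task: the force
#' transducer is sampled on a fixed tick (10 ms on the behavioral hardware)
#' and reported in grams. Sample `i` is stamped at `(i - 1) * sample_period_ms`
#' milliseconds from session start.
#'
#' @param samples Numeric vector of non-negative forces (grams), one per tick.
#' @param sample_period_ms Sampling period in milliseconds (default 10).
#' @param session_id Optional identifier carried through to trial logs.
#' @return An object of class `force_trace`.
#' @examples
#' tr <- force_trace(c(0, 5, 20, 80, 40, 0))
#' length(tr$samples)
#' @export
force_trace <- function(samples, sample_period_ms = 10, session_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("force trace must contain at least one sample")
  if (anyNA(samples)) stop("force trace contains missing samples")
  if (any(samples < 0)) stop("forces must be non-negative")
  if (!is.numeric(sample_period_ms) || length(sample_period_ms) != 1L ||
      !is.finite(sample_period_ms) || sample_period_ms <= 0) {
    stop("sample_period_ms must be a single positive number")
  }
  structure(
    list(samples = samples, sample_period_ms = sample_period_ms,
         session_id = as.character(session_id)),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  dur_s <- (length(x$samples) - 1L) * x$sample_period_ms / 1000
  cat(sprintf("<force_trace> %d samples @ %g ms (%.1f s), peak %.1f g\n",
              length(x$samples), x$sample_period_ms, dur_s, max(x$samples)))
  invisible(x)
}

#' Peak force of a trace segment
#'
#' The maximum force generated within a trial window; the task's primary
#' outcome measure.
#'
#' @param segment Numeric vector of forces (grams), non-empty.
#' @return Maximum force (grams).
#' @examples
#' peak_force(c(0, 10, 55, 30))
#' @export
peak_force <- function(segment) {
  if (is.list(segment) && inherits(segment, "force_trace")) segment <- segment$samples
  if (length(segment) < 1L) stop("empty segment")
  max(as.numeric(segment))
}

#' Detect trials on a force trace
#'
#' Scans a sampled force trace and segments it into discrete pull trials,
#' reproducing the automated task logic: a trial initiates at the first
#' eligible sample at or above `init_threshold` (10 g on the task), a fixed
#' response window (2 s) opens, and the peak force within the closed window
#' `[init_time, init_time + window_ms]` is recorded. Samples inside an open
#' window never start a new trial, and after a window closes the force must
#' fall below `init_threshold` for at least one sample before a new trial can
#' initiate (re-arm rule), so one sustained pull cannot spawn back-to-back
#' trials. A window truncated by the end of the session is kept and flagged.
#'
#' @param trace A [force_trace()].
#' @param init_threshold Trial initiation force in grams (default 10).
#' @param window_ms Response window in milliseconds (default 2000).
#' @return A data frame with one row per trial: `trial_index`, `init_time_ms`,
#'   `peak_force_g`, `peak_time_ms`, `truncated`.
#' @examples
#' f <- numeric(300)
#' f[101:130] <- seq(10, 80, length.out = 30)   # pull starting at t = 1000 ms
#' trials <- detect_trials(force_trace(f))
#' trials$peak_force_g
#' @export
detect_trials <- function(trace, init_threshold = 10, window_ms = 2000) {
  stopifnot(inherits(trace, "force_trace"))
  if (init_threshold <= 0) stop("init_threshold must be positive")
  if (window_ms <= 0) stop("window_ms must be positive")
  f <- trace$samples
  dt <- trace$sample_period_ms
  n <- length(f)
  t_ms <- (seq_len(n) - 1L) * dt

  init_t <- numeric(0); pk <- numeric(0); pk_t <- numeric(0); trunc <- logical(0)
  i <- 1L
  armed <- TRUE
  while (i <= n) {
    if (f[i] >= init_threshold && armed) {
      t0 <- t_ms[i]
      # closed window: samples with time <= t0 + window_ms
      j_end <- min(n, i + floor(window_ms / dt))
      seg <- f[i:j_end]
      k <- which.max(seg)
      init_t <- c(init_t, t0)
      pk <- c(pk, seg[k])
      pk_t <- c(pk_t, t_ms[i + k - 1L])
      trunc <- c(trunc, t0 + window_ms > t_ms[n])
      i <- j_end + 1L
      armed <- FALSE
    } else {
      if (f[i] < init_threshold) armed <- TRUE
      i <- i + 1L
    }
  }
  data.frame(
    trial_index = seq_along(init_t),
    init_time_ms = init_t,
    peak_force_g = pk,
    peak_time_ms = pk_t,
    truncated = trunc
  )
}

#' Read / write a force-trace CSV
#'
#' The trace dialect has a header and two columns, `t_ms` and `force_g`, one
#' row per tick. Reading rejects traces whose timestamps are not uniformly
#' spaced.
#'
#' @param path File path.
#' @return `read_force_trace()` returns a [force_trace()].
#' @export
read_force_trace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_ms", "force_g")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("force-trace CSV missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) >= 2L) {
    steps <- diff(d$t_ms)
    if (any(abs(steps - steps[1]) > 1e-9)) stop("non-uniform sampling in force-trace CSV")
    period <- steps[1]
  } else {
    period <- 10
  }
  force_trace(d$force_g, sample_period_ms = period)
}

#' @rdname read_force_trace
#' @param trace A [force_trace()] to serialize.
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  n <- length(trace$samples)
  utils::write.csv(
    data.frame(t_ms = (seq_len(n) - 1L) * trace$sample_period_ms,
               force_g = trace$samples),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
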