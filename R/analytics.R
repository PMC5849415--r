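#' Weekly peak-force summary per animal
#'
#' Mean peak pull force over all trials in each animal-week, plus success
#' rate (fraction of rewarded trials), trial and stimulation counts. Weeks
#' with zero trials are omitted (they carry no rows in the log).
#'
#' @param trials Trial-log data frame (see [read_trial_log()] for the
#'   dialect), or a `clv_protocol` object.
#' @return Data frame with one row per `animal_id` x `week`: `group`,
#'   `mean_peak_force_g`, `success_rate`, `n_trials`, `n_stimulations`.
#' @export
weekly_peak_force <- function(trials) {
  trials <- .as_trials(trials)
  sp <- split(trials, list(trials$animal_id, trials$week), drop = TRUE)
  out <- lapply(sp, function(d) {
    data.frame(
      animal_id = d$animal_id[1], group = d$group[1], week = d$week[1],
      mean_peak_force_g = mean(d$peak_force_g),
      success_rate = mean(d$rewarded),
      n_trials = nrow(d),
      n_stimulations = sum(d$stimulated),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$animal_id, out$week), ]
}

.as_trials <- function(x) {
  if (inherits(x, "clv_protocol")) x$trials else x
}

#' Stimulation-to-success timing of a session
#'
#' For every stimulation in a session, the absolute interval between the
#' stimulation time and the peak time of the nearest "most successful" trial,
#' where the reference set is the top 20% of the session's trials ranked by
#' peak force (mirroring the Top-20% trigger definition). Summary gives mean,
#' SD and median across stimulations; the median is the robust headline
#' because a minority of stimulations can fall far from any reference trial.
#'
#' @param session Trial-log data frame for one session (one `animal_id`,
#'   `week`, `session`).
#' @return A list with `intervals_s` (per-stimulation, seconds) and `summary`
#'   (`mean_s`, `sd_s`, `median_s`, `n`); intervals are `NULL` and summary
#'   `NA` when the session has no stimulation or no qualifying trial.
#' @export
stim_to_success_latency <- function(session) {
  session <- .as_trials(session)
  stims <- session$stim_time_ms[session$stimulated]
  n_top <- ceiling(0.2 * nrow(session))
  if (length(stims) == 0L || n_top == 0L) {
    return(list(intervals_s = NULL,
                summary = c(mean_s = NA_real_, sd_s = NA_real_,
                            median_s = NA_real_, n = 0)))
  }
  ord <- order(session$peak_force_g, decreasing = TRUE)
  top_times <- session$peak_time_ms[ord[seq_len(n_top)]]
  iv <- vapply(stims, function(st) min(abs(st - top_times)), numeric(1)) / 1000
  list(intervals_s = iv,
       summary = c(mean_s = mean(iv),
                   sd_s = if (length(iv) > 1L) stats::sd(iv) else NA_real_,
                   median_s = stats::median(iv), n = length(iv)))
}

#' Pooled stimulation-to-success timing across sessions
#'
#' Applies [stim_to_success_latency()] to every session in a trial log and
#' pools the per-stimulation intervals.
#'
#' @param trials Trial-log data frame or `clv_protocol`.
#' @return A list with `intervals_s` and `summary` as in
#'   [stim_to_success_latency()].
#' @export
pooled_stim_latency <- function(trials) {
  trials <- .as_trials(trials)
  sp <- split(trials, list(trials$animal_id, trials$week, trials$session),
              drop = TRUE)
  iv <- unlist(lapply(sp, function(d) stim_to_success_latency(d)$intervals_s))
  if (is.null(iv) || length(iv) == 0L) {
    return(list(intervals_s = NULL,
                summary = c(mean_s = NA_real_, sd_s = NA_real_,
                            median_s = NA_real_, n = 0)))
  }
  list(intervals_s = iv,
       summary = c(mean_s = mean(iv),
                   sd_s = if (length(iv) > 1L) stats::sd(iv) else NA_real_,
                   median_s = stats::median(iv), n = length(iv)))
}

#' Recovery and percent benefit over rehabilitation alone
#'
#' Per-animal recovery is the final-week mean peak force minus the
#' post-injury (POST) mean peak force. Percent benefit normalizes each
#' animal's recovery to the mean recovery of the rehabilitation-alone group:
#' `100 * recovery / mean(rehab-alone recoveries)`.
#'
#' @param trials Trial-log data frame or `clv_protocol`.
#' @param post_week,final_week Week labels of the post-injury baseline and
#'   the final therapy week (defaults `"POST"` and the lexicographically last
#'   therapy week present).
#' @param reference_group Group label used as the normalizer (default
#'   `"REHAB_ALONE"`).
#' @return Data frame per animal: `group`, `recovery_g`, `percent_benefit`.
#'   Percent benefit is `NA` (with a warning) if the reference group's mean
#'   recovery is not positive.
#' @export
percent_benefit <- function(trials, post_week = "POST", final_week = NULL,
                            reference_group = "REHAB_ALONE") {
  w <- weekly_peak_force(trials)
  if (is.null(final_week)) {
    tw <- sort(unique(w$week[grepl("^W[0-9]+$", w$week)]))
    if (length(tw) == 0L) stop("no therapy weeks in log; supply final_week")
    final_week <- tw[order(as.integer(sub("^W", "", tw)))][length(tw)]
  }
  post <- w[w$week == post_week, c("animal_id", "group", "mean_peak_force_g")]
  fin <- w[w$week == final_week, c("animal_id", "mean_peak_force_g")]
  m <- merge(post, fin, by = "animal_id", suffixes = c("_post", "_final"))
  m$recovery_g <- m$mean_peak_force_g_final - m$mean_peak_force_g_post
  ref <- m$recovery_g[m$group == reference_group]
  if (length(ref) == 0L) stop("reference group ", reference_group, " absent from log")
  ref_mean <- mean(ref)
  if (ref_mean <= 0) {
    warning("reference-group mean recovery is not positive; percent benefit undefined")
    m$percent_benefit <- NA_real_
  } else {
    m$percent_benefit <- 100 * m$recovery_g / ref_mean
  }
  m[, c("animal_id", "group", "recovery_g", "percent_benefit")]
}

#' First session meeting the proficiency criterion
#'
#' Proficiency is ten consecutive sessions in which more than 85% of trials
#' exceed 120 g. Returns the (1-based) index of the earliest session closing
#' such a run, or `NA` if the criterion is never met.
#'
#' @param session_fractions Numeric vector: per-session fraction of trials
#'   with peak force above 120 g, in session order. Alternatively a trial-log
#'   data frame, from which the fractions are computed per session.
#' @param criterion Required fraction (default 0.85, strict).
#' @param n_consecutive Required run length (default 10).
#' @return Integer session index or `NA_integer_`.
#' @export
proficiency_check <- function(session_fractions, criterion = 0.85,
                              n_consecutive = 10L) {
  if (is.data.frame(session_fractions)) {
    d <- session_fractions
    key <- interaction(d$animal_id, d$week, d$session, drop = TRUE)
    key <- factor(key, levels = unique(key))
    session_fractions <- as.numeric(
      tapply(d$peak_force_g > 120, key, mean)
    )
  }
  ok <- session_fractions > criterion
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= n_consecutive) return(i)
  }
  NA_integer_
}

#' Group-level descriptive tables
#'
#' Per-group, per-week mean and SEM of an animal-level weekly summary
#' variable. SEM is `NA` for groups of one.
#'
#' @param weekly Output of [weekly_peak_force()].
#' @param var Summary column to aggregate (default `"mean_peak_force_g"`).
#' @return Data frame `group`, `week`, `mean`, `sem`, `n_animals`.
#' @export
group_descriptives <- function(weekly, var = "mean_peak_force_g") {
  sp <- split(weekly, list(weekly$group, weekly$week), drop = TRUE)
  out <- lapply(sp, function(d) {
    x <- d[[var]]
    data.frame(
      group = d$group[1], week = d$week[1], mean = mean(x),
      sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
      n_animals = length(x), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$group, out$week), ]
}
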