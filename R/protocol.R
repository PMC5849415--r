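#' Study timeline
#'
#' The simulated study follows the behavioral arc of the rehabilitation
#' experiment: a pre-injury assessment (`PRE`, two days of two 30-min
#' sessions), the contusion injury, a post-injury baseline (`POST`, two days),
#' then six weeks of rehabilitative training (five days per week, two sessions
#' per day) with closed-loop stimulation in every therapy week except the
#' final one, which runs stimulation-off to probe lasting effects.
#'
#' @param pre_days,post_days Assessment days before/after injury (default 2).
#' @param therapy_weeks Number of therapy weeks (default 6).
#' @param stim_off_final_week Disable stimulation in the last therapy week
#'   (default `TRUE`).
#' @return An object of class `clv_timeline`.
#' @export
clv_timeline <- function(pre_days = 2L, post_days = 2L, therapy_weeks = 6L,
                         stim_off_final_week = TRUE) {
  stopifnot(pre_days >= 0L, post_days >= 0L, therapy_weeks >= 1L)
  structure(
    list(pre_days = as.integer(pre_days), post_days = as.integer(post_days),
         therapy_weeks = as.integer(therapy_weeks),
         stim_off_final_week = isTRUE(stim_off_final_week)),
    class = "clv_timeline"
  )
}

#' Cohort specification
#'
#' @param groups Character vector of policy labels (see [policy_config()]).
#' @param n_per_group Animals per group (default 8).
#' @param rat Template [rat_state()] shared by all animals at enrollment.
#' @param params Shared [behavior_params()].
#' @return An object of class `clv_cohort`.
#' @export
clv_cohort <- function(groups = c("REHAB_ALONE", "TOP20", "TOP20_DELAYED",
                                  "BOTTOM20", "TOP50"),
                       n_per_group = 8L, rat = rat_state(),
                       params = behavior_params()) {
  stopifnot(all(groups %in% c("REHAB_ALONE", "TOP20", "TOP20_DELAYED",
                              "BOTTOM20", "TOP50")),
            n_per_group >= 1L, inherits(rat, "rat_state"),
            inherits(params, "behavior_params"))
  structure(
    list(groups = groups, n_per_group = as.integer(n_per_group),
         rat = rat, params = params),
    class = "clv_cohort"
  )
}

# run one block of training days for one animal; returns trials + rat
.run_block <- function(rat, config, params, animal_id, group, week,
                       n_days, session_offset = 0L) {
  out <- vector("list", n_days * params$sessions_per_day)
  k <- 0L
  for (d in seq_len(n_days)) {
    for (s in seq_len(params$sessions_per_day)) {
      k <- k + 1L
      res <- simulate_session(rat, config, params, animal_id = animal_id,
                              group = group, week = week,
                              session = session_offset + k)
      out[[k]] <- res$trials
      rat <- res$rat
    }
  }
  list(trials = do.call(rbind, out), rat = rat)
}

#' Simulate a full cohort across the study timeline
#'
#' Runs every animal through PRE assessment, injury, POST assessment and the
#' therapy weeks under its group's trigger policy. Stimulation is disabled
#' during PRE/POST and in the final therapy week. Each animal gets its own
#' derived RNG seed, so cohorts are reproducible and animals independent.
#'
#' @param cohort A [clv_cohort()].
#' @param timeline A [clv_timeline()].
#' @param seed Integer base seed.
#' @return An object of class `clv_protocol`: a list with `trials` (full
#'   trial log), `animals` (per-animal capability bookkeeping), `cohort`,
#'   `timeline`, `seed`.
#' @export
simulate_protocol <- function(cohort, timeline = clv_timeline(), seed = 1L) {
  stopifnot(inherits(cohort, "clv_cohort"), inherits(timeline, "clv_timeline"))
  params <- cohort$params
  all_trials <- list()
  animals <- list()
  idx <- 0L
  for (g in cohort$groups) {
    for (a in seq_len(cohort$n_per_group)) {
      idx <- idx + 1L
      animal_id <- sprintf("%s_%02d", g, a)
      set.seed((as.integer(seed) + 7919L * idx) %% .Machine$integer.max)
      rat <- cohort$rat
      blocks <- list()
      cap_pre <- rat$capability
      if (timeline$pre_days > 0L) {
        b <- .run_block(rat, policy_config("REHAB_ALONE"), params,
                        animal_id, g, "PRE", timeline$pre_days)
        blocks <- c(blocks, list(b$trials)); rat <- b$rat
      }
      rat <- apply_injury(rat)
      cap_post <- rat$capability
      if (timeline$post_days > 0L) {
        b <- .run_block(rat, policy_config("REHAB_ALONE"), params,
                        animal_id, g, "POST", timeline$post_days)
        blocks <- c(blocks, list(b$trials)); rat <- b$rat
      }
      for (w in seq_len(timeline$therapy_weeks)) {
        stim_on <- !(timeline$stim_off_final_week && w == timeline$therapy_weeks)
        cfg <- policy_config(g, stim_enabled = stim_on)
        b <- .run_block(rat, cfg, params, animal_id, g, sprintf("W%d", w),
                        params$days_per_week)
        blocks <- c(blocks, list(b$trials)); rat <- b$rat
      }
      all_trials[[idx]] <- do.call(rbind, blocks)
      animals[[idx]] <- data.frame(
        animal_id = animal_id, group = g,
        capability_pre = cap_pre, capability_post = cap_post,
        capability_final = rat$capability, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(trials = do.call(rbind, all_trials),
         animals = do.call(rbind, animals),
         cohort = cohort, timeline = timeline, seed = as.integer(seed)),
    class = "clv_protocol"
  )
}

#' @export
print.clv_protocol <- function(x, ...) {
  cat(sprintf("<clv_protocol> %d animals, %d groups, %d trials, seed %d\n",
              nrow(x$animals), length(unique(x$animals$group)),
              nrow(x$trials), x$seed))
  agg <- stats::aggregate(capability_final ~ group, data = x$animals, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-14s final capability %6.1f g\n", agg$group[i],
                agg$capability_final[i]))
  }
  invisible(x)
}
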