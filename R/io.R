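#' Read / write the trial-log CSV dialect
#'
#' One flat dialect shared by the simulator and the analytics:
#' `animal_id,group,week,session,trial_index,init_time_ms,peak_force_g,
#' peak_time_ms,reward_threshold_g,stim_threshold_g,rewarded,stimulated,
#' stim_time_ms`, with empty fields for absent values (e.g. no stimulation
#' threshold during the first ten trials). Reading validates the header and
#' reports missing columns by name.
#'
#' @param path File path.
#' @return `read_trial_log()` returns the trial-log data frame.
#' @export
read_trial_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "week", "session", "trial_index",
            "init_time_ms", "peak_force_g", "peak_time_ms",
            "reward_threshold_g", "stim_threshold_g", "rewarded",
            "stimulated", "stim_time_ms")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trial-log CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  for (k in c("animal_id", "group", "week")) d[[k]] <- as.character(d[[k]])
  d$rewarded <- as.logical(d$rewarded)
  d$stimulated <- as.logical(d$stimulated)
  d[, need]
}

#' @rdname read_trial_log
#' @param trials Trial-log data frame (or `clv_protocol`).
#' @export
write_trial_log <- function(trials, path) {
  trials <- .as_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# known config schema: name -> validator
.config_schema <- list(
  policy = function(x) x %in% c("REHAB_ALONE", "TOP20", "TOP20_DELAYED",
                                "BOTTOM20", "TOP50"),
  n_per_group = function(x) is.numeric(x) && x >= 1,
  seed = function(x) is.numeric(x),
  tau_s = function(x) is.numeric(x) && x > 0,
  stim_gain = function(x) is.numeric(x) && x >= 0,
  injury_multiplier = function(x) is.numeric(x) && x > 0 && x <= 1,
  baseline_learning_rate = function(x) is.numeric(x) && x >= 0,
  capability = function(x) is.numeric(x) && x > 0,
  capability_ceiling = function(x) is.numeric(x) && x > 0,
  mean_intertrial_s = function(x) is.numeric(x) && x > 0,
  peak_sdlog = function(x) is.numeric(x) && x > 0,
  session_min = function(x) is.numeric(x) && x > 0,
  therapy_weeks = function(x) is.numeric(x) && x >= 1,
  pre_days = function(x) is.numeric(x) && x >= 0,
  post_days = function(x) is.numeric(x) && x >= 0,
  stim_off_final_week = function(x) is.logical(x),
  groups = function(x) all(x %in% c("REHAB_ALONE", "TOP20", "TOP20_DELAYED",
                                    "BOTTOM20", "TOP50")),
  out_dir = function(x) is.character(x)
)

#' Read and validate a run-configuration YAML
#'
#' Unknown keys are rejected (typos fail loudly rather than silently using a
#' default); known keys are type-checked. Missing keys fall back to package
#' defaults downstream.
#'
#' @param path YAML file path.
#' @return Named list of validated settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (!isTRUE(all(.config_schema[[k]](cfg[[k]])))) {
      stop("invalid value for config key '", k, "'")
    }
  }
  cfg
}

#' Write the resolved configuration beside run outputs
#'
#' Serializes the fully resolved settings to YAML and returns the file's MD5
#' hash so outputs can be traced to the exact configuration that produced
#' them.
#'
#' @param cfg Named list of resolved settings.
#' @param path Output YAML path.
#' @return The MD5 hash (character) of the written file, invisibly attached
#'   to the path via the `config_hash` attribute.
#' @export
write_resolved_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  hash <- unname(tools::md5sum(path))
  structure(invisible(path), config_hash = hash)
}

#' @rdname write_resolved_config
#' @export
config_hash <- function(path) unname(tools::md5sum(path))
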