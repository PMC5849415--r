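test_that("weekly peak force is the mean over all trials in the week", {
  log1 <- make_log(c(100, 120, 140))
  w <- weekly_peak_force(log1)
  expect_equal(w$mean_peak_force_g, 120)

  two <- rbind(make_log(rep(80, 10), session = 1),
               make_log(rep(80, 10), session = 2))
  expect_equal(weekly_peak_force(two)$mean_peak_force_g, 80)
  expect_equal(weekly_peak_force(two)$n_trials, 20L)
})

test_that("weekly summaries match a brute-force recomputation on a random log", {
  set.seed(71)
  logs <- do.call(rbind, lapply(1:4, function(a) {
    do.call(rbind, lapply(c("PRE", "W1", "W2"), function(wk) {
      make_log(runif(sample(5:30, 1), 5, 150), week = wk,
               animal = paste0("a", a), stimulated = NA)
    }))
  }))
  logs$stimulated <- runif(nrow(logs)) < 0.2
  w <- weekly_peak_force(logs)
  for (i in seq_len(nrow(w))) {
    rows <- logs[logs$animal_id == w$animal_id[i] & logs$week == w$week[i], ]
    expect_equal(w$mean_peak_force_g[i], sum(rows$peak_force_g) / nrow(rows))
    expect_equal(w$n_stimulations[i], sum(rows$stimulated))
    expect_equal(w$success_rate[i] * w$n_trials[i], sum(rows$rewarded))
  }
  expect_true(all(w$n_stimulations <= w$n_trials))
})

test_that("stimulation coincident with the only top trial gives zero latency", {
  log1 <- make_log(c(50, 60, 200), stimulated = c(FALSE, FALSE, TRUE),
                   stim_time = c(NA, NA, 2 * 20000 + 300))
  res <- stim_to_success_latency(log1)
  expect_equal(unname(res$summary["median_s"]), 0)
  expect_equal(res$intervals_s, 0)
})

test_that("latency uses the nearest top-20%-by-peak trial", {
  # 10 trials, peaks make trials 5 and 9 the top 20%; stim on trial 6
  peaks <- c(20, 30, 25, 35, 200, 40, 30, 22, 180, 28)
  stim <- rep(FALSE, 10); stim[6] <- TRUE
  st_time <- rep(NA_real_, 10); st_time[6] <- 5 * 20000 + 2000
  log1 <- make_log(peaks, stimulated = stim, stim_time = st_time)
  res <- stim_to_success_latency(log1)
  # top trials peak at t = 4*20000+300 and 8*20000+300; stim at 102000
  expect_equal(unname(res$intervals_s), min(abs(102000 - c(80300, 160300))) / 1000)
})

test_that("sessions without stimulation or qualifying trials are flagged absent", {
  res <- stim_to_success_latency(make_log(c(50, 60, 70)))
  expect_null(res$intervals_s)
  expect_true(is.na(res$summary["mean_s"]))
})

test_that("percent benefit normalizes recovery to the rehab-alone mean", {
  mk_animal <- function(id, group, post_mean, final_mean) {
    rbind(make_log(rep(post_mean, 5), week = "POST", animal = id, group = group),
          make_log(rep(final_mean, 5), week = "W6", animal = id, group = group))
  }
  logs <- rbind(
    mk_animal("r1", "REHAB_ALONE", 40, 60),   # recovery 20
    mk_animal("r2", "REHAB_ALONE", 40, 80),   # recovery 40; ref mean = 30
    mk_animal("t1", "TOP20", 40, 70),         # recovery 30 -> 100%
    mk_animal("t2", "TOP20", 40, 100)         # recovery 60 -> 200%
  )
  pb <- percent_benefit(logs)
  expect_equal(pb$percent_benefit[pb$animal_id == "t1"], 100)
  expect_equal(pb$percent_benefit[pb$animal_id == "t2"], 200)
  # a null effect leaves every group at ~100% on average
  expect_equal(mean(pb$percent_benefit[pb$group == "REHAB_ALONE"]), 100)
})

test_that("percent benefit is undefined when the reference recovery is not positive", {
  mk_animal <- function(id, group, post_mean, final_mean) {
    rbind(make_log(rep(post_mean, 5), week = "POST", animal = id, group = group),
          make_log(rep(final_mean, 5), week = "W6", animal = id, group = group))
  }
  logs <- rbind(mk_animal("r1", "REHAB_ALONE", 40, 40),
                mk_animal("t1", "TOP20", 40, 70))
  expect_warning(pb <- percent_benefit(logs), "undefined")
  expect_true(all(is.na(pb$percent_benefit)))
})

test_that("proficiency requires ten consecutive qualifying sessions", {
  expect_equal(proficiency_check(rep(0.9, 10)), 10L)
  expect_true(is.na(proficiency_check(c(rep(0.9, 9), 0.8, rep(0.9, 5)))))
  expect_equal(proficiency_check(rep(1, 12)), 10L)
  expect_equal(proficiency_check(c(0.2, rep(0.9, 10))), 11L)
  # threshold is strict: exactly 85% does not qualify
  expect_true(is.na(proficiency_check(rep(0.85, 10))))
})

test_that("group descriptives handle singletons and ties", {
  w <- data.frame(
    animal_id = c("a", "b", "c"), group = c("G1", "G2", "G2"),
    week = "W1", mean_peak_force_g = c(50, 70, 70),
    success_rate = 1, n_trials = 10, n_stimulations = 0
  )
  g <- group_descriptives(w)
  expect_true(is.na(g$sem[g$group == "G1"]))
  expect_equal(g$sem[g$group == "G2"], 0)
  expect_equal(g$mean[g$group == "G2"], 70)

  set.seed(72)
  w2 <- data.frame(
    animal_id = paste0("a", 1:30),
    group = sample(c("G1", "G2"), 30, TRUE), week = "W1",
    mean_peak_force_g = runif(30, 20, 150)
  )
  g2 <- group_descriptives(w2)
  for (i in seq_len(nrow(g2))) {
    x <- w2$mean_peak_force_g[w2$group == g2$group[i]]
    expect_equal(g2$mean[i], mean(x))
    expect_equal(g2$sem[i], sd(x) / sqrt(length(x)))
  }
})

test_that("analytics are pure functions of the serialized log", {
  set.seed(73)
  res <- simulate_session(rat_state(capability = 40), policy_config("TOP20"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(res$trials, path)
  back <- read_trial_log(path)
  w1 <- weekly_peak_force(res$trials)
  w2 <- weekly_peak_force(back)
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_equal(pooled_stim_latency(res$trials)$summary,
               pooled_stim_latency(back)$summary, tolerance = 1e-12)
})
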