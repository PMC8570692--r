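test_that("task_config validates durations, mixtures and counts", {
  expect_s3_class(task_config(), "task_config")
  expect_error(task_config(odor_duration = 0), "positive")
  expect_error(task_config(iti_rate = -1), "positive")
  expect_error(task_config(mixtures = c(0.5, 0.85)), "descending")
  expect_error(task_config(mixtures = c(1, 0.5)), "inside")
  expect_error(task_config(trials_per_odor_probe = 0), "positive integer")
})

test_that("truncated-exponential ITIs stay in (0, max] and match the closed-form mean", {
  x <- sample_iti(1e5, rate = 0.3, iti_max = 30, seed = 11)
  expect_true(all(x > 0 & x <= 30))
  # E[X | X <= M] = 1/rate - M exp(-rate M) / (1 - exp(-rate M))
  m_true <- 1 / 0.3 - 30 * exp(-9) / (1 - exp(-9))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - m_true), 4 * se)
  # rate -> large pushes draws toward 0
  expect_lt(mean(sample_iti(1000, rate = 100, iti_max = 30, seed = 1)), 0.05)
  expect_error(sample_iti(10, rate = 0), "positive")
  expect_error(sample_iti(10, iti_max = -1), "positive")
})

test_that("ITI hazard is flat away from the truncation boundary", {
  x <- sample_iti(2e5, seed = 3)
  # empirical hazard in 1 s bins over [0, 15]: survivors and events per bin
  edges <- 0:15
  haz <- vapply(seq_len(length(edges) - 1L), function(i) {
    at_risk <- sum(x >= edges[i])
    events <- sum(x >= edges[i] & x < edges[i + 1])
    events / at_risk
  }, numeric(1))
  expect_lt(diff(range(haz)) / mean(haz), 0.15)
})

test_that("trial counts per phase are exact and the timeline respects the protocol", {
  cfg <- task_config(group = "air_puff", seed = 4)
  trials <- generate_trial_table(cfg)
  per_session <- table(trials$session)
  expect_identical(as.integer(per_session[as.character(1:10)]),
                   rep(200L, 10))                     # 4 odors x 50
  expect_identical(as.integer(per_session[c("11", "22")]),
                   rep(236L, 2))                      # 4 x 53 + 3 x 8
  expect_identical(nrow(trials), 10L * 200L + 236L + 10L * 200L + 236L)

  # timing invariants
  expect_equal(trials$odor_off - trials$odor_on,
               rep(cfg$odor_duration, nrow(trials)))
  reinf <- !is.na(trials$outcome_time)
  expect_equal(trials$outcome_time[reinf] - trials$odor_off[reinf],
               rep(cfg$trace_delay, sum(reinf)))
  for (s in unique(trials$session)) {
    on <- trials$odor_on[trials$session == s]
    expect_true(!is.unsorted(on, strictly = TRUE))
    gaps <- diff(on) - (cfg$vacuum_time + cfg$post_vacuum_delay)
    expect_true(all(gaps > 0 & gaps <= cfg$iti_max + 1e-9))
  }

  # probe mixture trials are unreinforced; D is reinforced only with air puff
  mix <- trials[trials$odor == "mix", ]
  expect_true(all(mix$phase == "probe"))
  expect_true(all(mix$outcome == "none"))
  expect_true(all(trials$outcome[trials$odor == "D"] == "air_puff"))
  no_puff <- generate_trial_table(task_config(group = "no_air_puff", seed = 4))
  expect_true(all(no_puff$outcome[no_puff$odor == "D"] == "none"))
})

test_that("reversal sessions swap the A/B outcome contingencies", {
  trials <- generate_trial_table(task_config(seed = 9))
  cond <- trials[trials$phase == "conditioning", ]
  rev <- trials[trials$phase == "reversal", ]
  expect_true(all(cond$outcome[cond$odor == "A"] == "sucrose"))
  expect_true(all(cond$outcome[cond$odor == "B"] == "denatonium"))
  expect_true(all(rev$outcome[rev$odor == "A"] == "denatonium"))
  expect_true(all(rev$outcome[rev$odor == "B"] == "sucrose"))
  # second probe follows the reversed contingency
  probe2 <- trials[trials$phase == "probe" & trials$session > 11, ]
  expect_true(all(probe2$outcome[probe2$odor == "A"] == "denatonium"))
})

test_that("zero configured sessions give an empty table", {
  cfg <- task_config(n_conditioning = 0, n_reversal = 0)
  expect_identical(nrow(generate_trial_table(cfg)), 0L)
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- task_config(n_conditioning = 1, n_reversal = 0, seed = 21)
  t1 <- generate_trial_table(cfg)
  t2 <- generate_trial_table(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_licks(t1, lick_params(), seed = 5),
                   simulate_licks(t2, lick_params(), seed = 5))
  s1 <- t1[t1$session == 1, ]; attr(s1, "config") <- cfg
  expect_identical(simulate_unit(s1, unit_spec(3, tagged = TRUE)),
                   simulate_unit(s1, unit_spec(3, tagged = TRUE)))
})

test_that("simulated lick rates recover the configured condition rates", {
  trials <- make_trials(rep(c(1, 0.5, 0), each = 400))
  par <- lick_params(rate_sucrose = 8, rate_denatonium = 0.4)
  licks <- simulate_licks(trials, par, seed = 31)
  rates <- epoch_lick_rate(licks, trials)
  for (p in c(1, 0.5, 0)) {
    r <- rates$lick_rate[rates$sucrose_prop == p]
    truth <- 0.4 + (8 - 0.4) * p
    se <- sqrt(truth / (2 * length(r)))     # Poisson count in a 2 s window
    expect_lt(abs(mean(r) - truth), 3.5 * se + 1e-9)
  }
  # multiplier 1 for both groups leaves no group difference in expectation
  par1 <- lick_params(group_multiplier = 1)
  expect_equal(lick_rate_per_trial_public(make_trials(0.5), par1),
               lick_rate_per_trial_public(make_trials(0.5, group = "air_puff"),
                                          par1))
  expect_error(lick_params(rate_sucrose = -1), "non-negative")
})

test_that("air-puff group multiplier depresses mixture and sucrose cue licking", {
  par <- lick_params(group_multiplier = 0.7)
  for (p in c(0.15, 0.5, 0.85, 1)) {
    ctl <- lick_rate_per_trial_public(make_trials(p), par)
    puf <- lick_rate_per_trial_public(make_trials(p, group = "air_puff"), par)
    expect_lt(puf, ctl)
  }
  # monotone in sucrose proportion
  r <- vapply(c(0, 0.15, 0.5, 0.85, 1),
              function(p) lick_rate_per_trial_public(make_trials(p), par),
              numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("extinction decay lowers the lick rate across probe repeats", {
  trials <- make_trials(rep(0.5, 8), phase = "probe")
  par <- lick_params(extinction_decay = 0.3)
  r <- lick_rate_per_trial_public(trials, par, all_trials = TRUE)
  expect_true(all(diff(r) < 0))
  expect_equal(r[8] / r[1], exp(-0.3 * 7))
})

test_that("simulate_unit emits the 100-pulse identification protocol", {
  trials <- make_trials(rep(c(1, 0), 5))
  rec <- simulate_unit(trials, unit_spec(1, tagged = TRUE), seed = 7)
  proto <- rec$pulses[!rec$pulses$triggered, ]
  expect_identical(nrow(proto), 100L)
  # 10 trains of 10 pulses at 10 Hz, 10 s between train onsets
  starts <- sort(proto$pulse_time)[seq(1, 100, by = 10)]
  expect_equal(diff(starts), rep(10, 9))
  within <- sort(proto$pulse_time)[1:10]
  expect_equal(diff(within), rep(0.1, 9), tolerance = 1e-12)
})

test_that("unresponsive tag parameters evoke nothing", {
  trials <- make_trials(rep(1, 5))
  rec <- simulate_unit(trials, unit_spec(1, tagged = TRUE, tag_reliability = 0),
                       seed = 3)
  res <- optotag_unit(rec$spikes, rec$pulses)
  # only chance coincidences of spontaneous spikes remain
  expect_lt(res$reliability, 0.2)
  expect_false(res$tagged)
})

test_that("cue-period spike rates recover the configured modulation", {
  trials <- make_trials(rep(c(1, 0), 250))
  rec <- simulate_unit(trials, unit_spec(1, baseline_rate = 5, cue_gain = 1),
                       seed = 13)
  r <- align_spikes(rec$spikes, trials)
  cue_rate <- function(sel) {
    mean(vapply(r$aligned[sel], function(s) sum(s >= 0 & s < 2), numeric(1))) / 2
  }
  suc <- trials$sucrose_prop == 1
  se10 <- sqrt(10 / (2 * sum(suc)))
  expect_lt(abs(cue_rate(suc) - 10), 3.5 * se10)    # baseline * (1 + gain)
  se5 <- sqrt(5 / (2 * sum(!suc)))
  expect_lt(abs(cue_rate(!suc) - 5), 3.5 * se5)
  base <- mean(vapply(r$aligned, function(s) sum(s >= -1 & s < 0), numeric(1)))
  expect_lt(abs(base - 5), 3.5 * sqrt(5 / nrow(trials)))
})

test_that("cluster features have the configured geometry", {
  fx <- simulate_cluster_features(c(200, 300), n_dims = 3, separation = 6,
                                  seed = 2)
  expect_identical(dim(fx$features), c(500L, 3L))
  expect_identical(as.integer(table(fx$labels)), c(200L, 300L))
  centers <- apply(fx$features, 2, function(col) tapply(col, fx$labels, mean))
  expect_equal(unname(centers["2", 1] - centers["1", 1]), 6, tolerance = 0.3)
  expect_error(simulate_cluster_features(100, n_dims = 0), "positive integer")
  expect_error(simulate_cluster_features(100, separation = -1), "separation")
})
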