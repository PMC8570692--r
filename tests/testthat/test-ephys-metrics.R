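test_that("spike alignment maps session times to trial-relative times", {
  trials <- make_trials(c(1, 0, 1))           # odor onsets at 5, 10, 15
  r <- align_spikes(c(5.5, 9.2, 14.0, 16.9, 30), trials, window = c(-1, 2))
  expect_equal(r$aligned[[1]], 0.5)
  expect_equal(r$aligned[[2]], -0.8)
  expect_equal(r$aligned[[3]], c(-1.0, 1.9))
  # empty train keeps trial structure
  r0 <- align_spikes(numeric(0), trials)
  expect_identical(lengths(r0$aligned), rep(0L, 3L))
  expect_error(align_spikes(1:3, trials[0, ]), "non-empty")
})

test_that("PSTH matches definitions and the generator rate", {
  # one trial, one spike, 0.1 s bins -> 10 spikes/s in its bin
  r1 <- make_raster(list(0.55), window = c(0, 2))
  p1 <- psth(r1, bin_width = 0.1, baseline_window = c(0, 0.5))
  expect_equal(p1$rate[p1$bin_start == 0.5], 10)
  expect_equal(sum(p1$rate > 0), 1L)
  # no spikes -> all-zero
  expect_equal(psth(make_raster(list(numeric(0), numeric(0))))$rate,
               rep(0, 30))
  # homogeneous unit: every bin near the true rate, normalized trace near 0
  trials <- make_trials(rep(1, 400))
  rec <- simulate_unit(trials, unit_spec(1, baseline_rate = 5, cue_gain = 0),
                       seed = 15)
  p <- psth(align_spikes(rec$spikes, trials))
  se_bin <- sqrt(5 / (400 * 0.1))
  expect_true(all(abs(p$rate - 5) < 4.5 * se_bin))
  expect_lt(mean(abs(p$rate_baseline_subtracted)), 3 * se_bin)
  expect_error(psth(make_raster(list(1), window = c(0, 1)), bin_width = 0.3),
               "divide")
})

test_that("binned auROC matches hand-computed pair counts", {
  # counts A = (2,3,3), B = (1,3,0) in the single [0,1) bin:
  # 6 wins + 2 ties/2 over 9 pairs = 7/9
  aligned <- list(rep(0.5, 2), rep(0.5, 3), rep(0.5, 3),
                  rep(0.5, 1), rep(0.5, 3), numeric(0))
  r <- make_raster(aligned, window = c(0, 1))
  prof <- binned_auroc(r, 1:3, 4:6, bin_width = 1)
  expect_equal(prof$auroc, 7 / 9)
  # identical distributions -> 0.5; complete separation -> 1
  ident <- binned_auroc(make_raster(rep(list(rep(0.5, 2)), 6), c(0, 1)),
                        1:3, 4:6, bin_width = 1)
  expect_equal(ident$auroc, 0.5)
  sep <- binned_auroc(make_raster(c(rep(list(rep(0.5, 5)), 3),
                                    rep(list(numeric(0)), 3)), c(0, 1)),
                      1:3, 4:6, bin_width = 1)
  expect_equal(sep$auroc, 1)
  expect_error(binned_auroc(r, 1, 4:6), "at least 2")
})

test_that("auROC is antisymmetric and invariant to monotone count transforms", {
  set.seed(12)
  for (i in 1:20) {
    a <- rpois(7, 3); b <- rpois(9, 2)
    ab <- gonogo:::auroc_counts(a, b)
    ba <- gonogo:::auroc_counts(b, a)
    expect_equal(ab + ba, 1)
    expect_identical(gonogo:::auroc_counts(a^3 + 2, b^3 + 2), ab)
    expect_identical(gonogo:::auroc_counts(exp(a), exp(b)), ab)
  }
})

test_that("classification thresholds and tie-break follow the rules", {
  fake_profile <- function(values) {
    out <- data.frame(bin_start = seq(0, by = 0.1,
                                      length.out = length(values)),
                      bin_end = seq(0.1, by = 0.1,
                                    length.out = length(values)),
                      auroc = values)
    attr(out, "window") <- c(0, 0.1 * length(values))
    class(out) <- c("auroc_profile", "data.frame")
    out
  }
  flat <- fake_profile(rep(0.5, 20))
  expect_identical(classify_discriminative(flat), "none")
  one_up <- fake_profile(c(rep(0.5, 19), 0.72))
  expect_identical(classify_discriminative(one_up), "excited")
  conflict <- fake_profile(c(0.25, 0.71, rep(0.5, 18)))
  expect_identical(classify_discriminative(conflict), "inhibited")  # 0.25 excursion wins
  conflict2 <- fake_profile(c(0.29, 0.78, rep(0.5, 18)))
  expect_identical(classify_discriminative(conflict2), "excited")
  # bins outside the cue window are ignored
  pre_cue <- fake_profile(c(0.9, rep(0.5, 19)))
  expect_identical(classify_discriminative(pre_cue, cue_window = c(0.1, 2)),
                   "none")
})

test_that("cue-evoked rate changes are detected with the right sign", {
  trials <- make_trials(rep(1, 60))
  up <- simulate_unit(trials, unit_spec(1, baseline_rate = 5, cue_gain = 1),
                      seed = 2)
  res_up <- cue_response_change(align_spikes(up$spikes, trials))
  expect_identical(res_up$direction, "increase")
  expect_gt(res_up$change, 0)
  down <- simulate_unit(trials, unit_spec(2, baseline_rate = 6,
                                          cue_gain = -0.6), seed = 3)
  res_down <- cue_response_change(align_spikes(down$spikes, trials))
  expect_identical(res_down$direction, "decrease")
  expect_lt(res_down$change, 0)
  # identical cue and baseline rates per trial: zero change, degenerate p
  same <- make_raster(rep(list(c(-0.5, 0.5)), 10))
  res0 <- cue_response_change(same, cue_window = c(0, 1),
                              baseline_window = c(-1, 0))
  expect_equal(res0$change, 0)
  expect_true(res0$degenerate)
  expect_identical(res0$direction, "none")
})

test_that("a configured +5 spikes/s cue gain is detected in most seeds", {
  trials <- make_trials(rep(1, 50))
  hits <- vapply(1:40, function(s) {
    rec <- simulate_unit(trials, unit_spec(1, baseline_rate = 5, cue_gain = 1),
                         seed = 700 + s)
    res <- cue_response_change(align_spikes(rec$spikes, trials))
    res$direction == "increase"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
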