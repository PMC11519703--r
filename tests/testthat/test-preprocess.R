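test_that("timestamp trimming reproduces the 2-SD oracle", {
  # evenly spaced points: max |z| = 1.486 < 2, nothing removed
  even <- toy_labeled(seq(0, 900, by = 100))
  res <- trim_timestamps(even)
  expect_equal(nrow(res$samples), 10)
  expect_equal(res$report$n_removed, 0)

  # a gross outlier: direct mean/sd oracle says only it exceeds 2 SD
  ts <- c(0:9, 10000)
  z <- abs(ts - mean(ts)) / sd(ts)
  expect_true(sum(z > 2) == 1 && z[11] > 2)
  res2 <- trim_timestamps(toy_labeled(ts))
  expect_equal(res2$samples$timestamp_ms, 0:9)
  expect_equal(res2$report$n_removed, 1)

  # single- and two-sample trials pass through (sd undefined / n < 3)
  res3 <- trim_timestamps(toy_labeled(5))
  expect_equal(nrow(res3$samples), 1)
  res4 <- trim_timestamps(toy_labeled(c(0, 1e6)))
  expect_equal(nrow(res4$samples), 2)

  # count conservation and report consistency
  both <- rbind(toy_labeled(ts, trial = "t01"),
                toy_labeled(seq(0, 900, 100), trial = "t02"))
  res5 <- trim_timestamps(both)
  expect_equal(res5$report$n_input, 21)
  expect_equal(nrow(res5$samples) + res5$report$n_removed, 21)
  expect_equal(res5$report$fraction_removed, 1 / 21)

  # provenance: trimming twice is refused
  expect_error(trim_timestamps(res5$samples), "exactly once")
})

test_that("trimming agrees with a grouped stats::sd oracle on noisy data", {
  set.seed(3)
  gz <- do.call(rbind, lapply(1:12, function(i)
    toy_labeled(sort(runif(sample(3:40, 1), 0, 12000)),
                trial = sprintf("t%02d", i))))
  res <- trim_timestamps(gz)
  oracle_keep <- unlist(lapply(split(gz$timestamp_ms, gz$trial_id),
                               function(t) {
    if (length(t) < 3 || sd(t) == 0) rep(TRUE, length(t))
    else abs(t - mean(t)) <= 2 * sd(t)
  }))
  expect_equal(nrow(res$samples), sum(oracle_keep))
  expect_equal(res$samples$timestamp_ms, gz$timestamp_ms[oracle_keep])
})

test_that("RT trimming drops inaccurate trials then 2-SD outliers", {
  # 20 trials: 2 inaccurate, 1 extreme RT among the remaining 18
  tt <- toy_trials(trial_ids = sprintf("t%02d", 1:20))
  tt$accurate <- c(rep(TRUE, 18), FALSE, FALSE)
  tt$rt_ms <- c(rep(3000, 8), rep(3200, 9), 60000, 3100, 3100)
  # oracle: within the 18 accurate, only the 60000 exceeds 2 SD
  acc_rt <- tt$rt_ms[tt$accurate]
  expect_equal(sum(abs(acc_rt - mean(acc_rt)) > 2 * sd(acc_rt)), 1)
  res <- trim_rts(tt)
  expect_equal(res$report$n_inaccurate, 2)
  expect_equal(res$report$n_rt_outlier, 1)
  expect_equal(nrow(res$trials), 17)
  expect_equal(res$report$fraction_removed, 3 / 20)
  expect_false(60000 %in% res$trials$rt_ms)

  # identical RTs: sd = 0, nothing removed in step 2
  tt2 <- toy_trials(trial_ids = sprintf("t%02d", 1:6))
  res2 <- trim_rts(tt2)
  expect_equal(nrow(res2$trials), 6)

  # a fully inaccurate participant is removed with a warning
  tt3 <- toy_trials(trial_ids = sprintf("t%02d", 1:4))
  tt3$accurate <- FALSE
  expect_warning(res3 <- trim_rts(tt3), "all trials removed")
  expect_equal(nrow(res3$trials), 0)

  expect_error(trim_rts(res$trials), "exactly once")
})

test_that("binning uses half-open 100-ms bins and drops empty bins", {
  gz <- toy_labeled(c(0, 50, 99.999, 100, 150, 350),
                    labels = c("target", "target", "target",
                               "foil", "target", "foil"))
  tt <- toy_trials()
  bins <- bin_gaze(gz, tt)
  expect_equal(bins$bin_index, c(0, 1, 3))
  # bin 0: 3 target, 0 foil; bin 1: exactly-100 sample goes here
  expect_equal(bins$proportion[bins$bin_index == 0], 1)
  expect_equal(bins$n_target[bins$bin_index == 1], 1)
  expect_equal(bins$n_foil[bins$bin_index == 1], 1)
  expect_equal(bins$proportion[bins$bin_index == 1], 0.5)
  expect_equal(bins$proportion[bins$bin_index == 3], 0)
  # bin 2 has no samples and is absent
  expect_false(2 %in% bins$bin_index)
  # rel_bin is anchored at the disambiguation bin (2000 ms -> bin 20)
  expect_equal(bins$rel_bin, bins$bin_index - 20)

  # 3 target + 1 foil = 0.75
  gz2 <- toy_labeled(c(10, 20, 30, 40),
                     labels = c("target", "target", "target", "foil"))
  expect_equal(bin_gaze(gz2, tt)$proportion, 0.75)

  expect_error(bin_gaze(gz, tt, window = c(0, 12000), width = 70),
               "divide")
})

test_that("none samples are excluded from denominators unless asked", {
  gz <- toy_labeled(c(10, 20, 30, 40),
                    labels = c("target", "none", "none", "foil"))
  tt <- toy_trials()
  b1 <- bin_gaze(gz, tt)
  expect_equal(b1$n_obs, 2)
  expect_equal(b1$proportion, 0.5)
  b2 <- bin_gaze(gz, tt, include_none = TRUE)
  expect_equal(b2$n_obs, 4)
  expect_equal(b2$proportion, 0.25)
})

test_that("binning conserves labeled samples and emits 120 full-grid bins", {
  st <- simulate_study(fast_config())
  lb <- label_stream(st$gaze, st$trials, st$viewports)
  tr <- trim_timestamps(lb)
  bins <- bin_gaze(tr$samples, st$trials)
  in_win <- tr$samples$timestamp_ms >= 0 & tr$samples$timestamp_ms < 12000
  n_tf <- sum(tr$samples$aoi_label[in_win] %in% c("target", "foil"))
  expect_equal(sum(bins$n_obs), n_tf)
  expect_equal(sum(bins$n_target) + sum(bins$n_foil), n_tf)
  expect_true(all(bins$proportion >= 0 & bins$proportion <= 1))
  expect_true(all(bins$n_obs >= 1))
  # the lab stream covers the whole window: 120 distinct bins, levels 0..119
  expect_equal(sort(unique(bins$bin_index[bins$modality == "lab"])), 0:119)
  expect_equal(levels(bins$bin_f), as.character(0:119))
})

test_that("sqrt transform is exact and rejects nonpositive RTs", {
  tt <- toy_trials(trial_ids = c("a", "b"))
  tt$rt_ms <- c(2500, 3600)
  out <- transform_rt(tt)
  expect_equal(out$sqrt_rt, c(50, 60))
  expect_equal(out$rt_ms, c(2500, 3600))
  tt$rt_ms[1] <- 0
  expect_error(transform_rt(tt), "positive")
})
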