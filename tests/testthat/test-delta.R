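make_bins <- function(df) {
  df$bin_f <- factor(df$bin_index)
  df
}

two_group_bins <- function(props_c, props_p, modality = "lab",
                           structure = "active") {
  rbind(
    data.frame(participant_id = "c1", group = "control", modality = modality,
               trial_id = "t01", structure = structure,
               bin_index = seq_along(props_c) - 1, n_target = 10,
               n_foil = 2, n_obs = 12, proportion = props_c),
    data.frame(participant_id = "p1", group = "pwa", modality = modality,
               trial_id = "t01", structure = structure,
               bin_index = seq_along(props_p) - 1, n_target = 10,
               n_foil = 2, n_obs = 12, proportion = props_p))
}

test_that("delta is the control-minus-pwa mean and is antisymmetric", {
  b <- two_group_bins(c(0.9, 0.8), c(0.6, 0.8))
  d <- compute_delta(b)
  expect_equal(d$delta, c(0.3, 0.0))

  # identical group streams: delta identically zero
  b0 <- two_group_bins(c(0.7, 0.7, 0.7), c(0.7, 0.7, 0.7))
  expect_true(all(compute_delta(b0)$delta == 0))

  # swapping group labels negates every delta exactly
  b2 <- b
  b2$group <- ifelse(b$group == "control", "pwa", "control")
  expect_equal(compute_delta(b2)$delta, -d$delta)
})

test_that("delta matches a hand-rolled group-mean oracle on simulated data", {
  st <- simulate_study(fast_config())
  lb <- label_stream(st$gaze, st$trials, st$viewports)
  bins <- bin_gaze(lb, st$trials)
  d <- compute_delta(bins)
  expect_true(all(abs(d$delta) <= 1))
  # oracle: plain tapply means per cell
  exp_bins <- bins[bins$structure %in% c("active", "passive", "locative"), ]
  key <- with(exp_bins, paste(modality, structure, bin_index))
  mc <- tapply(exp_bins$proportion[exp_bins$group == "control"],
               key[exp_bins$group == "control"], mean)
  mp <- tapply(exp_bins$proportion[exp_bins$group == "pwa"],
               key[exp_bins$group == "pwa"], mean)
  common <- intersect(names(mc), names(mp))
  oracle <- as.vector(mc[common]) - as.vector(mp[common])
  got <- setNames(d$delta, paste(d$modality, d$structure, d$bin_index))
  expect_equal(unname(got[common]), oracle, tolerance = 1e-12)
  # a modality with only one group errors
  solo <- bins[bins$group == "pwa" | bins$modality == "lab", ]
  expect_error(compute_delta(solo[solo$modality == "web", ]),
               "missing one of the groups")
})

test_that("delta model finds equal slopes null and shifted-web interaction", {
  bins <- 0:59
  lab_delta <- 0.002 * bins
  series <- rbind(
    data.frame(bin_index = bins, structure = "all", modality = "lab",
               delta = lab_delta, n_control_cells = 5, n_pwa_cells = 5),
    data.frame(bin_index = bins, structure = "all", modality = "web",
               delta = lab_delta, n_control_cells = 5, n_pwa_cells = 5))
  fit <- suppressWarnings(fit_delta_model(series))  # noiseless fixture
  cf <- fit$coefficients
  expect_equal(cf$estimate[grep(":", cf$term)], 0, tolerance = 1e-12)

  # web = lab shifted later in time => positive bin x web interaction on a
  # rising-then-falling series
  hump <- function(b) 0.25 * exp(-((b - 30) / 12)^2)
  s2 <- rbind(
    data.frame(bin_index = bins, structure = "all", modality = "lab",
               delta = hump(bins), n_control_cells = 5, n_pwa_cells = 5),
    data.frame(bin_index = bins, structure = "all", modality = "web",
               delta = hump(bins - 6), n_control_cells = 5, n_pwa_cells = 5))
  fit2 <- suppressWarnings(fit_delta_model(s2))
  cf2 <- fit2$coefficients
  expect_gt(cf2$estimate[grep(":", cf2$term)], 0)

  w <- capture_warnings(fit_delta_model(transform(series, delta = 0.1)))
  expect_true(any(grepl("constant", w)))
  expect_error(fit_delta_model(series[series$bin_index == 0, ]),
               "at least 2 bins")
})

test_that("delta model interaction has nominal type-I error on noise", {
  set.seed(99)
  reps <- 200
  sig <- replicate(reps, {
    s <- rbind(
      data.frame(bin_index = 0:29, structure = "all", modality = "lab",
                 delta = rnorm(30, 0, 0.05), n_control_cells = 5,
                 n_pwa_cells = 5),
      data.frame(bin_index = 0:29, structure = "all", modality = "web",
                 delta = rnorm(30, 0, 0.05), n_control_cells = 5,
                 n_pwa_cells = 5))
    cf <- fit_delta_model(s)$coefficients
    cf$p[grep(":", cf$term)] < 0.05
  })
  rate <- mean(sig)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / reps) + 0.02)
})

test_that("lag estimators are exact on constructed shifts", {
  hump <- function(b) exp(-((b - 40) / 10)^2) + 0.2 * sin(b / 9)
  base <- setNames(hump(0:119), 0:119)
  shifted <- setNames(hump((0:119) - 6), 0:119)
  for (m in c("peak", "dip", "xcorr")) {
    expect_equal(estimate_lag(base, base, method = m)$lag_bins, 0L)
    expect_equal(estimate_lag(base, shifted, method = m)$lag_bins, 6L)
  }
  # shift equivariance across several shifts for xcorr
  for (k in c(-9, -3, 2, 11)) {
    sh <- setNames(hump((0:119) - k), 0:119)
    expect_equal(estimate_lag(base, sh, method = "xcorr")$lag_bins,
                 as.integer(k))
  }
  expect_equal(estimate_lag(base, shifted, method = "peak")$lag_ms, 600)
  expect_error(estimate_lag(base[1:3], base[1:3]), "too short")
})

test_that("missing bins are interpolated before lag estimation", {
  hump <- function(b) exp(-((b - 30) / 8)^2)
  full <- setNames(hump(0:79), 0:79)
  holes <- full[-c(10, 25, 26, 50, 71)]
  shifted <- setNames(hump((0:79) - 4), 0:79)
  expect_equal(estimate_lag(holes, shifted, method = "xcorr")$lag_bins, 4L)
  # data.frame input (compute_delta shape) is accepted
  df_lab <- data.frame(bin_index = 0:79, delta = as.numeric(full))
  df_web <- data.frame(bin_index = 0:79, delta = as.numeric(shifted))
  expect_equal(estimate_lag(df_lab, df_web)$lag_bins, 4L)
})
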