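test_that("saturated two-cell fit recovers closed-form logits", {
  d <- data.frame(proportion = c(0.5, 0.8), x = factor(c("a", "b")),
                  n_obs = c(100, 100))
  fit <- fit_binwise(d, proportion ~ x)
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$estimate[2], log(4), tolerance = 1e-8)
})

test_that("IRLS matches brute-force likelihood maximization", {
  set.seed(21)
  n <- 150
  d <- data.frame(
    g = factor(sample(c("c", "p"), n, TRUE)),
    m = factor(sample(c("lab", "web"), n, TRUE)),
    b = factor(sample(0:3, n, TRUE)))
  eta <- 0.3 - 0.5 * (d$g == "p") + 0.2 * (d$m == "web") +
    0.15 * as.integer(as.character(d$b))
  d$n_obs <- sample(2:30, n, TRUE)
  d$proportion <- rbinom(n, d$n_obs, plogis(eta)) / d$n_obs
  fit <- fit_binwise(d, proportion ~ g + m + b)
  X <- model.matrix(~ g + m + b, d)
  beta_star <- oracle_logit_fit(X, d$proportion, d$n_obs)
  expect_equal(fit$coefficients$estimate, unname(beta_star),
               tolerance = 1e-6)

  # cross-check dispersion and SEs against stats::glm quasibinomial
  gfit <- glm(proportion ~ g + m + b, data = d, family = quasibinomial(),
              weights = n_obs)
  expect_equal(fit$coefficients$estimate, unname(coef(gfit)),
               tolerance = 1e-7)
  expect_equal(fit$dispersion, summary(gfit)$dispersion, tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(summary(gfit)$coefficients[, 2]), tolerance = 1e-6)
})

test_that("identical proportions give zero slopes and no overdispersion", {
  d <- data.frame(proportion = rep(0.6, 8),
                  x = factor(rep(c("a", "b"), 4)), n_obs = 10)
  fit <- fit_binwise(d, proportion ~ x)
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-10)
  expect_lte(fit$dispersion, 1e-8)
})

test_that("dispersion scales SEs but not point estimates", {
  set.seed(5)
  d <- data.frame(proportion = runif(40, 0.2, 0.9),
                  x = factor(rep(c("a", "b"), 20)), n_obs = 20)
  fit <- fit_binwise(d, proportion ~ x)
  unweighted_se <- fit$coefficients$se / sqrt(fit$dispersion)
  # refit pretending dispersion were 1: estimates identical
  spec <- model_spec(proportion ~ x, "quasibinomial", weights = "n_obs")
  fit2 <- fit_binwise(d, spec)
  expect_equal(fit$coefficients$estimate, fit2$coefficients$estimate)
  expect_gt(fit$dispersion, 1)
  expect_true(all(fit$coefficients$se > unweighted_se))
})

test_that("empty design cells are reported as inestimable", {
  d <- data.frame(proportion = c(0.5, 0.6, 0.7),
                  g = factor(c("c", "c", "p")),
                  m = factor(c("lab", "web", "lab")), n_obs = 10)
  expect_error(fit_binwise(d, proportion ~ g * m), "inestimable")
  expect_error(model_spec(proportion ~ g, "quasibinomial", random = "pid"),
               "random")
})

test_that("accuracy model recovers closed-form log-odds on a 2x2 toy", {
  counts <- data.frame(
    structure = rep(c("active", "passive"), each = 2),
    modality = rep(c("lab", "web"), 2),
    n_correct = c(90, 80, 60, 40), n_total = 100)
  rows <- do.call(rbind, lapply(seq_len(4), function(i) {
    k <- counts[i, ]
    data.frame(group = "pwa", participant_id = "p01",
               trial_id = sprintf("tr%d", i),
               structure = k$structure, modality = k$modality,
               accurate = rep(c(TRUE, FALSE),
                              c(k$n_correct, k$n_total - k$n_correct)))
  }))
  fit <- fit_accuracy(rows, accurate ~ structure * modality, random = FALSE)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), qlogis(0.9), tolerance = 1e-6)
  expect_equal(unname(est["structurepassive"]), qlogis(0.6) - qlogis(0.9),
               tolerance = 1e-6)
  expect_equal(unname(est["modalityweb"]), qlogis(0.8) - qlogis(0.9),
               tolerance = 1e-6)
  expect_equal(unname(est["structurepassive:modalityweb"]),
               (qlogis(0.4) - qlogis(0.6)) - (qlogis(0.8) - qlogis(0.9)),
               tolerance = 1e-6)

  allsame <- rows; allsame$accurate <- TRUE
  expect_error(fit_accuracy(allsame, random = FALSE), "degenerate response")
})

test_that("accuracy model flags a simulated passive deficit", {
  # default pwa logits put passive a full logit below active
  hits <- replicate(30, {
    s <- sample.int(1e6, 1)
    tt <- simulate_study(sim_config(n_control = 0, n_pwa = 16, seed = s),
                         gaze = FALSE)$trials
    fit <- suppressWarnings(fit_accuracy(tt))
    cf <- fit$coefficients
    i <- grep("passive", cf$term)
    c(est = cf$estimate[i], sig = cf$p[i] < 0.05)
  })
  expect_lt(mean(hits["est", ]), 0)
  expect_gt(mean(hits["sig", ]), 0.8)
})

test_that("RT model reduces to cell-mean differences without random effects", {
  tt <- data.frame(group = "control", participant_id = "c1",
                   trial_id = sprintf("t%d", 1:40),
                   structure = "active",
                   modality = rep(c("lab", "web"), each = 20),
                   rt_ms = c(rep(2500, 20), rep(1600, 20)),
                   accurate = TRUE)
  tt <- transform_rt(tt)
  fit <- suppressWarnings(fit_rt(tt, sqrt_rt ~ modality, random = FALSE))
  expect_equal(fit$coefficients$estimate[2], 40 - 50, tolerance = 1e-10)
})

test_that("RT model recovers an injected sqrt-scale modality shift", {
  set.seed(60)
  ests <- replicate(25, {
    base <- expand.grid(participant_id = sprintf("s%02d", 1:32),
                        trial_id = sprintf("t%02d", 1:45),
                        modality = c("lab", "web"))
    psd <- rnorm(32, 0, 4); isd <- rnorm(45, 0, 2)
    base$sqrt_rt <- 65 +
      psd[as.integer(factor(base$participant_id))] +
      isd[as.integer(factor(base$trial_id))] +
      (base$modality == "web") * -40 + rnorm(nrow(base), 0, 6)
    fit <- suppressWarnings(fit_rt(base, sqrt_rt ~ modality))
    fit$coefficients$estimate[2]
  })
  expect_lt(abs(mean(ests) - (-40)), 3)
  # variance explained summaries are present and ordered
  st <- simulate_study(fast_config(), gaze = FALSE)
  tr <- trim_rts(st$trials)$trials
  fit <- fit_rt(transform_rt(tr))
  expect_gt(fit$r2_conditional, fit$r2_marginal)
  expect_gt(fit$r2_marginal, 0)
})
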