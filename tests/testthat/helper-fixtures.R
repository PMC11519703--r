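# Shared fixtures: small configurations and hand-built tables.

# fast config: web sampling for both noise regimes kept, lab thinned to make
# unit-test simulations cheap; full-rate configs are reserved for the
# acceptance checks that need them
fast_config <- function(seed = 42, ...) {
  sim_config(n_control = 2, n_pwa = 2,
             lab_interval_ms = 25, lab_interval_sd_ms = 40,
             seed = seed, ...)
}

toy_viewport <- function(w = 1920, h = 1080) list(width_px = w, height_px = h)

# hand-built labeled gaze table: one participant, one trial, label mode
toy_labeled <- function(ts, labels = rep("target", length(ts)),
                        pid = "p01", trial = "t01", modality = "lab") {
  data.frame(participant_id = pid, trial_id = trial, modality = modality,
             timestamp_ms = ts, x_px = NA_real_, y_px = NA_real_,
             aoi_label = labels, stringsAsFactors = FALSE)
}

toy_trials <- function(trial_ids = "t01", target_side = "left",
                       pid = "p01", modality = "lab") {
  data.frame(participant_id = pid, group = "control", modality = modality,
             session = paste(pid, modality, sep = ":"),
             trial_id = trial_ids, structure = "active",
             filler_type = NA_character_, target_side = target_side,
             disamb_ms = 2000, rt_ms = 4000, accurate = TRUE,
             stringsAsFactors = FALSE)
}

# independent quasibinomial oracle: maximize the weighted binomial
# log-likelihood directly over coefficients
oracle_logit_fit <- function(X, y, w) {
  nll <- function(beta) {
    mu <- plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}
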