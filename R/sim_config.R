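#' Simulation configuration for a synthetic lab + web eye-tracking study
#'
#' Bundles every tunable parameter of the synthetic-study generator: group
#' sizes, modality-specific sampling-interval distributions, the injected web
#' temporal lag, the disambiguation-locked gaze ramp (per-group onset delay,
#' rate, and per-group-by-structure asymptote), behavioral generators
#' (accuracy logits, lognormal reaction times), spatial noise, dropout, and
#' the trial clock.
#'
#' Inter-sample intervals are drawn from lognormal distributions
#' moment-matched to the configured mean and standard deviation, so realized
#' mean intervals converge to `lab_interval_ms` / `web_interval_ms` while
#' reproducing the heavy right skew of webcam sampling (SD larger than the
#' mean). The probability that a sample lands on the target picture is 0.5
#' until `disambiguation + ramp_onset_delay_ms[group] + web_lag_ms` (the lag
#' applies to the web modality only), then rises along a logistic ramp toward
#' the group-by-structure asymptote; an optional late decay pulls the aphasia
#' (pwa) group's curve back toward 0.5 after `pwa_late_decay_ms`.
#'
#' @param n_control,n_pwa participants per group (each tested in both
#'   modalities).
#' @param lab_interval_ms,lab_interval_sd_ms mean and SD (ms) of lab
#'   inter-sample intervals; defaults 2.3 and 13.91.
#' @param web_interval_ms,web_interval_sd_ms mean and SD (ms) of web
#'   inter-sample intervals; defaults 49 and 162.2.
#' @param web_lag_ms temporal lag (ms) added to the web modality's gaze ramp
#'   onset; default 600.
#' @param ramp_onset_delay_ms named numeric, per-group delay (ms) between
#'   disambiguation and ramp onset.
#' @param ramp_rate named numeric, per-group logistic rate (1/ms).
#' @param asymptote named list (`control`, `pwa`) of per-structure asymptotic
#'   target proportions in `[0.5, 1]`.
#' @param pwa_late_decay_ms time (ms, trial clock) after which the pwa curve
#'   decays back toward 0.5; `Inf` (default) disables the decay.
#' @param late_decay_rate exponential decay rate (1/ms) for the late decay.
#' @param accuracy_logit named list (`control`, `pwa`) of per-structure
#'   log-odds of a correct response.
#' @param rt_meanlog_base,rt_meanlog_group,rt_meanlog_structure,rt_meanlog_mode
#'   additive components of the lognormal reaction-time location (log-ms).
#' @param rt_sdlog lognormal reaction-time scale (residual).
#' @param rt_participant_sdlog,rt_item_sdlog SDs of participant- and
#'   item-level shifts on the reaction-time location (log-ms), giving the
#'   mixed models real random-intercept variance to estimate.
#' @param accuracy_participant_sd,accuracy_item_sd SDs of participant- and
#'   item-level shifts on the accuracy log-odds.
#' @param spatial_noise_px named numeric, per-modality SD (px) of Gaussian
#'   coordinate noise around the AOI center.
#' @param dropout_prob named numeric, per-modality probability that a sample
#'   lands outside both AOIs.
#' @param trial_duration_ms gaze recording window per trial (ms); default
#'   12000.
#' @param disamb_window_ms named list of `c(lo, hi)` windows (ms) from which
#'   per-trial disambiguation times are drawn, per structure type.
#' @param web_viewports matrix-like data.frame of candidate web viewports
#'   (columns `width_px`, `height_px`); one is assigned per participant.
#' @param seed master integer seed; fully determines the generated study.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_control = 2, n_pwa = 2, seed = 42)
#' cfg$web_lag_ms
sim_config <- function(n_control = 16L,
                       n_pwa = 16L,
                       lab_interval_ms = 2.3,
                       lab_interval_sd_ms = 13.91,
                       web_interval_ms = 49,
                       web_interval_sd_ms = 162.2,
                       web_lag_ms = 600,
                       ramp_onset_delay_ms = c(control = 150, pwa = 900),
                       ramp_rate = c(control = 0.004, pwa = 0.0015),
                       asymptote = list(
                         control = c(active = 0.90, passive = 0.88,
                                     locative = 0.85, filler = 0.90),
                         pwa = c(active = 0.80, passive = 0.70,
                                 locative = 0.72, filler = 0.78)),
                       pwa_late_decay_ms = Inf,
                       late_decay_rate = 5e-4,
                       accuracy_logit = list(
                         control = c(active = 4.6, passive = 4.6,
                                     locative = 4.6, filler = 4.6),
                         pwa = c(active = 1.8, passive = 0.8,
                                 locative = 1.2, filler = 2.2)),
                       rt_meanlog_base = log(4200),
                       rt_meanlog_group = c(control = 0, pwa = 0.22),
                       rt_meanlog_structure = c(active = 0, passive = 0.06,
                                                locative = 0.03, filler = 0),
                       rt_meanlog_mode = c(lab = 0, web = -0.12),
                       rt_sdlog = 0.25,
                       rt_participant_sdlog = 0.15,
                       rt_item_sdlog = 0.05,
                       accuracy_participant_sd = 0.5,
                       accuracy_item_sd = 0.3,
                       spatial_noise_px = c(lab = 15, web = 80),
                       dropout_prob = c(lab = 0.02, web = 0.10),
                       trial_duration_ms = 12000,
                       disamb_window_ms = list(
                         active = c(1600, 2400), passive = c(1600, 2400),
                         locative = c(1500, 2300), filler = c(1400, 2200)),
                       web_viewports = data.frame(
                         width_px = c(1920L, 1536L, 1366L, 1280L),
                         height_px = c(1080L, 864L, 768L, 800L)),
                       seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control), n_pwa = as.integer(n_pwa),
    lab_interval_ms = lab_interval_ms, lab_interval_sd_ms = lab_interval_sd_ms,
    web_interval_ms = web_interval_ms, web_interval_sd_ms = web_interval_sd_ms,
    web_lag_ms = web_lag_ms,
    ramp_onset_delay_ms = ramp_onset_delay_ms, ramp_rate = ramp_rate,
    asymptote = asymptote,
    pwa_late_decay_ms = pwa_late_decay_ms, late_decay_rate = late_decay_rate,
    accuracy_logit = accuracy_logit,
    rt_meanlog_base = rt_meanlog_base, rt_meanlog_group = rt_meanlog_group,
    rt_meanlog_structure = rt_meanlog_structure,
    rt_meanlog_mode = rt_meanlog_mode, rt_sdlog = rt_sdlog,
    rt_participant_sdlog = rt_participant_sdlog,
    rt_item_sdlog = rt_item_sdlog,
    accuracy_participant_sd = accuracy_participant_sd,
    accuracy_item_sd = accuracy_item_sd,
    spatial_noise_px = spatial_noise_px, dropout_prob = dropout_prob,
    trial_duration_ms = trial_duration_ms,
    disamb_window_ms = disamb_window_ms,
    web_viewports = web_viewports,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!all(ok)) stop("invalid sim_config: ", msg,
                                              call. = FALSE)
  chk(cfg$n_control >= 0 && cfg$n_pwa >= 0, "negative group size")
  chk(c(cfg$lab_interval_ms, cfg$web_interval_ms,
        cfg$lab_interval_sd_ms, cfg$web_interval_sd_ms) > 0,
      "sampling intervals and SDs must be strictly positive")
  chk(cfg$web_lag_ms >= 0, "web_lag_ms must be nonnegative")
  chk(cfg$trial_duration_ms > 0, "trial_duration_ms must be positive")
  grp <- c("control", "pwa")
  str4 <- c("active", "passive", "locative", "filler")
  chk(all(grp %in% names(cfg$ramp_onset_delay_ms)) &&
        all(cfg$ramp_onset_delay_ms >= 0), "ramp_onset_delay_ms per group, >= 0")
  chk(all(grp %in% names(cfg$ramp_rate)) && all(cfg$ramp_rate > 0),
      "ramp_rate per group, > 0")
  for (g in grp) {
    a <- cfg$asymptote[[g]]
    chk(all(str4 %in% names(a)) && all(a >= 0.5) && all(a <= 1),
        sprintf("asymptote[[%s]] must cover all structures, in [0.5, 1]", g))
    chk(all(str4 %in% names(cfg$accuracy_logit[[g]])),
        sprintf("accuracy_logit[[%s]] must cover all structures", g))
  }
  chk(all(c("lab", "web") %in% names(cfg$spatial_noise_px)) &&
        all(cfg$spatial_noise_px >= 0), "spatial_noise_px per modality, >= 0")
  chk(all(c("lab", "web") %in% names(cfg$dropout_prob)) &&
        all(cfg$dropout_prob >= 0 & cfg$dropout_prob < 1),
      "dropout_prob per modality, in [0, 1)")
  chk(cfg$rt_sdlog > 0, "rt_sdlog must be positive")
  chk(c(cfg$rt_participant_sdlog, cfg$rt_item_sdlog,
        cfg$accuracy_participant_sd, cfg$accuracy_item_sd) >= 0,
      "random-effect SDs must be nonnegative")
  for (s in str4) {
    w <- cfg$disamb_window_ms[[s]]
    chk(length(w) == 2 && w[1] <= w[2] && w[1] > 1000,
        "disambiguation windows must start after 1000 ms (audio onset)")
  }
  chk(nrow(cfg$web_viewports) >= 1 &&
        all(cfg$web_viewports$width_px > 0) &&
        all(cfg$web_viewports$height_px > 0), "web_viewports must be valid")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  participants: %d control + %d pwa (both modalities)\n",
              x$n_control, x$n_pwa))
  cat(sprintf("  sampling: lab %.3g ms (SD %.4g), web %.3g ms (SD %.4g)\n",
              x$lab_interval_ms, x$lab_interval_sd_ms,
              x$web_interval_ms, x$web_interval_sd_ms))
  cat(sprintf("  web lag: %g ms; trial window: 0-%g ms; seed: %d\n",
              x$web_lag_ms, x$trial_duration_ms, x$seed))
  invisible(x)
}
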