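# Synthetic dual-modality gaze streams.
#
# Target probability model: flat 0.5 until the effective onset
#   T0 = disambiguation + per-group delay + (web ? web_lag : 0),
# then a scaled logistic ramp 0.5 + (a - 0.5) * (2 / (1 + exp(-r (t - T0))) - 1)
# which leaves 0.5 continuously at T0 and saturates at the group-by-structure
# asymptote a. An optional late decay multiplies (p - 0.5) by
# exp(-late_decay_rate * (t - pwa_late_decay_ms)) for the pwa group.

.lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Expected target-gaze probability under the simulator
#'
#' The noise-free probability that a gaze sample at time `t` lands on the
#' target picture, for a given group, structure, and modality. Useful as the
#' ground truth when checking what the pipeline recovers from simulated data
#' (e.g. the true group-difference window or the injected web lag).
#'
#' @param t_ms numeric vector of times (ms, trial clock).
#' @param disamb_ms disambiguation time of the trial (ms).
#' @param group `"control"` or `"pwa"`.
#' @param structure structure type (one of the asymptote names).
#' @param modality `"lab"` or `"web"`.
#' @param config a [sim_config()].
#' @return numeric vector of probabilities.
#' @export
expected_proportion <- function(t_ms, disamb_ms, group, structure, modality,
                                config) {
  a <- config$asymptote[[group]][[structure]]
  t0 <- disamb_ms + config$ramp_onset_delay_ms[[group]] +
    if (modality == "web") config$web_lag_ms else 0
  .ramp_p(t_ms, rep_len(t0, length(t_ms)), rep_len(a, length(t_ms)),
          group, config)
}

# vectorized ramp: t0 and a may vary per sample (per-trial values repeated)
.ramp_p <- function(t, t0, a, group, config) {
  r <- config$ramp_rate[[group]]
  p <- rep(0.5, length(t))
  post <- t >= t0
  if (any(post)) {
    if (!is.finite(r)) {
      p[post] <- a[post]
    } else {
      p[post] <- 0.5 + (a[post] - 0.5) *
        (2 / (1 + exp(-r * (t[post] - t0[post]))) - 1)
    }
  }
  if (group == "pwa" && is.finite(config$pwa_late_decay_ms)) {
    late <- t > config$pwa_late_decay_ms
    p[late] <- 0.5 + (p[late] - 0.5) *
      exp(-config$late_decay_rate * (t[late] - config$pwa_late_decay_ms))
  }
  p
}

#' Simulate one trial's gaze stream
#'
#' Draws strictly increasing sample timestamps with the modality's lognormal
#' inter-sample intervals, then assigns each sample to the target or foil
#' picture with the time-varying probability of [expected_proportion()].
#' A `dropout_prob` fraction of samples lands outside both AOIs. Web-style
#' output is coordinate mode: the chosen AOI's center plus Gaussian noise
#' (`none` samples land in the inter-AOI gap); lab-style output carries AOI
#' labels directly, matching lab acquisition exports.
#'
#' Consumes the current RNG state; seed management lives in
#' [simulate_study()].
#'
#' @param trial one-row design (needs `disamb_ms`, `structure`,
#'   `target_side`).
#' @param config a [sim_config()].
#' @param group,modality generating condition.
#' @param viewport viewport for coordinate-mode output (web).
#' @return `data.frame` with `timestamp_ms` and either `aoi_label` (lab) or
#'   `x_px`, `y_px` (web).
#' @export
simulate_trial_gaze <- function(trial, config, group, modality,
                                viewport = NULL) {
  core <- .sim_trial_core(trial, config, group, modality)
  if (modality == "lab")
    return(data.frame(timestamp_ms = core$t,
                      aoi_label = c("target", "foil", "none")[core$role],
                      stringsAsFactors = FALSE))
  ctr <- .aoi_centers(viewport)
  idx <- .box_index(core$role, trial$target_side)
  n <- length(core$t)
  noise <- config$spatial_noise_px[["web"]]
  data.frame(timestamp_ms = core$t,
             x_px = ctr$cx[idx] + rnorm(n, 0, noise),
             y_px = ctr$cy + rnorm(n, 0, noise),
             stringsAsFactors = FALSE)
}

# role codes: 1 = target, 2 = foil, 3 = neither
.sim_trial_core <- function(trial, config, group, modality) {
  dur <- config$trial_duration_ms
  m <- if (modality == "lab") config$lab_interval_ms else config$web_interval_ms
  s <- if (modality == "lab") config$lab_interval_sd_ms else
    config$web_interval_sd_ms
  lp <- .lnorm_pars(m, s)
  n_est <- ceiling(dur / m * 1.25) + 30L
  t <- cumsum(rlnorm(n_est, lp[1], lp[2]))
  while (t[length(t)] < dur)
    t <- c(t, t[length(t)] + cumsum(rlnorm(n_est, lp[1], lp[2])))
  t <- t[t < dur]
  n <- length(t)
  if (n == 0L) return(list(t = numeric(0), role = integer(0)))
  p <- expected_proportion(t, trial$disamb_ms, group, trial$structure,
                           modality, config)
  dropped <- runif(n) < config$dropout_prob[[modality]]
  on_target <- !dropped & runif(n) < p
  role <- rep(2L, n)
  role[on_target] <- 1L
  role[dropped] <- 3L
  list(t = t, role = role)
}

# batched version of .sim_trial_core over a whole design (one RNG pass per
# block; per-trial top-up only when the pre-drawn intervals fall short)
.sim_block <- function(design, config, group, modality) {
  dur <- config$trial_duration_ms
  m <- if (modality == "lab") config$lab_interval_ms else config$web_interval_ms
  s <- if (modality == "lab") config$lab_interval_sd_ms else
    config$web_interval_sd_ms
  lp <- .lnorm_pars(m, s)
  K <- nrow(design)
  n_est <- as.integer(ceiling(dur / m * 1.4) + 30L)
  v <- rlnorm(n_est * K, lp[1], lp[2])
  cs <- cumsum(v)
  ends <- seq_len(K) * n_est
  off <- c(0, cs[ends[-K]])
  t <- cs - rep(off, each = n_est)
  trial_of <- rep(seq_len(K), each = n_est)
  block_tot <- cs[ends] - off
  keep <- t < dur
  short <- which(block_tot < dur)
  if (length(short)) {                  # rare top-up
    tl <- split(t[keep], factor(trial_of[keep], levels = seq_len(K)))
    for (j in short) {
      tj <- tl[[j]]
      last <- if (length(tj)) tj[length(tj)] else 0
      while (last < dur) {
        add <- last + cumsum(rlnorm(n_est, lp[1], lp[2]))
        tj <- c(tj, add)
        last <- add[length(add)]
      }
      tl[[j]] <- tj[tj < dur]
    }
    n_per <- lengths(tl)
    t_all <- unlist(tl, use.names = FALSE)
  } else {
    n_per <- tabulate(trial_of[keep], K)
    t_all <- t[keep]
  }
  n <- length(t_all)

  a_tab <- config$asymptote[[group]][design$structure]
  t0_tab <- design$disamb_ms + config$ramp_onset_delay_ms[[group]] +
    if (modality == "web") config$web_lag_ms else 0
  p <- .ramp_p(t_all, rep(t0_tab, n_per), rep(unname(a_tab), n_per),
               group, config)
  dropped <- runif(n) < config$dropout_prob[[modality]]
  on_target <- !dropped & runif(n) < p
  role <- rep(2L, n)
  role[on_target] <- 1L
  role[dropped] <- 3L
  list(t = t_all, role = role, n_per = n_per)
}

.box_index <- function(role, target_side) {
  # map target/foil/none roles onto left/right/gap box centers
  tgt_idx <- if (target_side == "left") 1L else 2L
  idx <- rep(3L - tgt_idx, length(role))
  idx[role == 1L] <- tgt_idx
  idx[role == 3L] <- 3L
  idx
}

.aoi_centers <- function(viewport) {
  aois <- compute_aois(viewport)
  list(cx = c((aois$left$x_start_px + aois$left$x_end_px) / 2,
              (aois$right$x_start_px + aois$right$x_end_px) / 2,
              aois$viewport$width_px / 2),
       cy = (aois$left$y_start_px + aois$left$y_end_px) / 2)
}

#' Simulate a complete two-modality study
#'
#' Generates a full synthetic study under `config`: a 65-trial design
#' ([build_design()]), one trial-table row per participant x modality x
#' trial (with lognormal reaction times and Bernoulli accuracy from the
#' configured logits), a per-participant viewport table, and (optionally)
#' the concatenated gaze streams. Every participant completes both the lab
#' and the web session. The master seed is split into per-participant
#' sub-seeds, so the output is bit-identical for identical configs.
#'
#' @param config a [sim_config()].
#' @param gaze if `FALSE`, skip gaze-stream generation (behavioral tables
#'   only); the trial table is unchanged either way.
#' @param modalities which sessions to generate; default both. Restricting
#'   to one modality is useful for reduced-scale Monte-Carlo checks that do
#'   not compare modalities.
#' @return object of class `gp_study`: list with `design`, `trials`,
#'   `viewports`, `gaze` (`NULL` when `gaze = FALSE`), and `config`.
#' @export
#' @examples
#' st <- simulate_study(sim_config(n_control = 1, n_pwa = 1, seed = 3),
#'                      gaze = FALSE)
#' nrow(st$trials)  # 2 participants x 2 modalities x 65 trials
simulate_study <- function(config, gaze = TRUE,
                           modalities = c("lab", "web")) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  validate_sim_config(config)
  n_part <- config$n_control + config$n_pwa
  if (n_part == 0L) stop("empty study: n_control + n_pwa must be positive")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  design_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  part_seeds <- sample.int(.Machine$integer.max - 1L, n_part)

  design <- build_design(seed = design_seed,
                         disamb_window_ms = config$disamb_window_ms)

  ids <- c(sprintf("c%02d", seq_len(config$n_control)),
           sprintf("p%02d", seq_len(config$n_pwa)))
  groups <- rep(c("control", "pwa"), c(config$n_control, config$n_pwa))

  set.seed(design_seed)  # viewport and item effects ride on the design stream
  vp_idx <- sample.int(nrow(config$web_viewports), n_part, replace = TRUE)
  item_rt <- rnorm(nrow(design), 0, config$rt_item_sdlog)
  item_acc <- rnorm(nrow(design), 0, config$accuracy_item_sd)
  viewports <- rbind(
    data.frame(participant_id = ids, modality = "lab",
               width_px = 1920L, height_px = 1080L),
    data.frame(participant_id = ids, modality = "web",
               width_px = config$web_viewports$width_px[vp_idx],
               height_px = config$web_viewports$height_px[vp_idx]))

  trial_list <- vector("list", n_part)
  gaze_list <- if (gaze) vector("list", n_part) else NULL
  gid_list <- if (gaze) vector("list", n_part * length(modalities)) else NULL
  for (i in seq_len(n_part)) {
    set.seed(part_seeds[i])
    pid <- ids[i]; grp <- groups[i]
    part_rt <- rnorm(1, 0, config$rt_participant_sdlog)
    part_acc <- rnorm(1, 0, config$accuracy_participant_sd)
    blocks <- lapply(modalities, function(md) {
      tt <- design
      ml <- config$rt_meanlog_base + config$rt_meanlog_group[[grp]] +
        config$rt_meanlog_structure[tt$structure] +
        config$rt_meanlog_mode[[md]] + part_rt + item_rt
      data.frame(
        participant_id = pid, group = grp, modality = md,
        session = paste(pid, md, sep = ":"),
        trial_id = tt$trial_id, structure = tt$structure,
        filler_type = tt$filler_type, target_side = tt$target_side,
        disamb_ms = tt$disamb_ms,
        rt_ms = rlnorm(nrow(tt), ml, config$rt_sdlog),
        accurate = runif(nrow(tt)) <
          plogis(unname(config$accuracy_logit[[grp]][tt$structure]) +
                   part_acc + item_acc),
        stringsAsFactors = FALSE)
    })
    trial_list[[i]] <- rbindlist(blocks)
    if (gaze) {
      vp_web <- viewports[viewports$participant_id == pid &
                            viewports$modality == "web", ]
      ctr <- .aoi_centers(vp_web)
      noise <- config$spatial_noise_px[["web"]]
      streams <- lapply(modalities, function(md) {
        blk <- .sim_block(design, config, grp, md)
        mdi <- match(md, modalities)
        gid0 <- ((i - 1L) * length(modalities) + (mdi - 1L)) * nrow(design)
        gid_list[[(i - 1L) * length(modalities) + mdi]] <<-
          rep(gid0 + seq_len(nrow(design)), blk$n_per)
        out <- data.table(
          participant_id = pid, trial_id = rep(design$trial_id, blk$n_per),
          modality = md, timestamp_ms = blk$t)
        if (md == "lab") {
          out[, aoi_label := c("target", "foil", "none")[blk$role]]
        } else {
          tgt_idx <- rep(ifelse(design$target_side == "left", 1L, 2L),
                         blk$n_per)
          idx <- 3L - tgt_idx                 # foil side
          idx[blk$role == 1L] <- tgt_idx[blk$role == 1L]
          idx[blk$role == 3L] <- 3L
          out[, `:=`(x_px = ctr$cx[idx] + rnorm(.N, 0, noise),
                     y_px = ctr$cy + rnorm(.N, 0, noise),
                     aoi_label = NA_character_)]
        }
        out
      })
      gaze_list[[i]] <- rbindlist(streams, fill = TRUE)
    }
  }

  trials <- setDF(rbindlist(trial_list))
  gz <- NULL
  if (gaze) {
    gz <- rbindlist(gaze_list, fill = TRUE)
    if (!"x_px" %in% names(gz)) gz[, `:=`(x_px = NA_real_, y_px = NA_real_)]
    if (!"aoi_label" %in% names(gz)) gz[, aoi_label := NA_character_]
    setcolorder(gz, intersect(c("participant_id", "trial_id", "modality",
                                "timestamp_ms", "x_px", "y_px", "aoi_label"),
                              names(gz)))
    setDF(gz)
    # precomputed trial-cell codes (see preprocess): avoids re-keying 10^7
    # rows downstream; any consumer may ignore or recompute them
    attr(gz, "cell_codes") <- list(
      gid = unlist(gid_list, use.names = FALSE),
      up = ids, um = modalities, ut = design$trial_id)
  }
  out <- list(design = design, trials = trials, viewports = viewports,
              gaze = gz, config = config)
  class(out) <- "gp_study"
  out
}

#' @export
print.gp_study <- function(x, ...) {
  cat("<gp_study>\n")
  cat(sprintf("  %d trial rows (%d participants x %d modalities x %d trials)\n",
              nrow(x$trials),
              length(unique(x$trials$participant_id)),
              length(unique(x$trials$modality)), nrow(x$design)))
  if (!is.null(x$gaze))
    cat(sprintf("  %s gaze samples\n", format(nrow(x$gaze), big.mark = ",")))
  invisible(x)
}
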