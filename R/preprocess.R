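# Trimming and binning rules:
#  * timestamps: within each trial, drop samples more than 2 sample-SDs
#    (n - 1 denominator) from the trial's mean timestamp; trials with fewer
#    than 3 samples or zero SD pass through untrimmed;
#  * reaction times: drop inaccurate trials, then, within each
#    participant-session, trials more than 2 SDs from the session mean;
#  * gaze: 100-ms half-open bins over 0-12,000 ms, proportions of target
#    samples out of target + foil; empty bins are absent from the output.
# Each trim is applied exactly once; provenance attributes guard re-trims.

.assert_untrimmed <- function(x, flag) {
  if (isTRUE(attr(x, flag)))
    stop("input already ", flag, ": each trim is applied exactly once")
}

# integer trial-cell codes (participant x modality x trial), memoized as an
# attribute so the trim -> bin chain codes the character keys only once
.compute_codes <- function(df) {
  up <- unique(df$participant_id)
  um <- unique(df$modality)
  ut <- unique(df$trial_id)
  gid <- (chmatch(as.character(df$participant_id), up) - 1L) *
    (length(um) * length(ut)) +
    (chmatch(as.character(df$modality), um) - 1L) * length(ut) +
    chmatch(as.character(df$trial_id), ut)
  list(gid = gid, up = up, um = um, ut = ut)
}

.codes_of <- function(df) {
  cc <- attr(df, "cell_codes")
  if (!is.null(cc) && length(cc$gid) == nrow(df)) cc else .compute_codes(df)
}

.decode_gid <- function(gid, cc) {
  nt <- length(cc$ut); nm <- length(cc$um)
  ti <- (gid - 1L) %% nt + 1L
  mi <- ((gid - 1L) %/% nt) %% nm + 1L
  pi_ <- (gid - 1L) %/% (nt * nm) + 1L
  list(participant_id = cc$up[pi_], modality = cc$um[mi],
       trial_id = cc$ut[ti])
}

.subset_frame <- function(df, keep) {
  out <- as.data.frame(lapply(df, function(col) col[keep]),
                       optional = TRUE, stringsAsFactors = FALSE)
  names(out) <- names(df)
  out
}

#' Trim gaze samples by per-trial timestamp dispersion
#'
#' Removes, within each participant x modality x trial, every sample whose
#' timestamp lies more than two sample standard deviations from the trial's
#' mean timestamp (two-sided). Trials with fewer than 3 samples, or with
#' zero timestamp SD, pass through untrimmed. The returned table carries a
#' `timestamp_trimmed` provenance attribute; feeding it back in errors, so
#' the 2-SD rule can never be applied twice.
#'
#' @param gaze labeled or raw gaze table with `participant_id`, `trial_id`,
#'   `modality`, `timestamp_ms`.
#' @return list with `samples` (the retained rows) and `report`
#'   (`n_input`, `n_removed`, `fraction_removed`, plus a per-modality
#'   breakdown).
#' @export
trim_timestamps <- function(gaze) {
  .assert_untrimmed(gaze, "timestamp_trimmed")
  n_in <- nrow(gaze)
  cc <- .codes_of(gaze)
  t <- gaze$timestamp_ms
  gmax <- length(cc$up) * length(cc$um) * length(cc$ut)
  n_g <- tabulate(cc$gid, gmax)
  s1 <- s2 <- numeric(gmax)
  r1 <- rowsum(t, cc$gid)
  r2 <- rowsum(t * t, cc$gid)
  gi <- as.integer(rownames(r1))
  s1[gi] <- r1; s2[gi] <- r2
  mu_g <- s1 / pmax(n_g, 1L)
  var_g <- (s2 - n_g * mu_g^2) / pmax(n_g - 1L, 1L)
  sd_g <- sqrt(pmax(var_g, 0))
  mu <- mu_g[cc$gid]; s <- sd_g[cc$gid]; n_of <- n_g[cc$gid]
  keep <- n_of < 3L | !is.finite(s) | s == 0 | abs(t - mu) <= 2 * s

  nt <- length(cc$ut)
  mi <- ((cc$gid - 1L) %/% nt) %% length(cc$um) + 1L
  by_mode <- data.frame(
    modality = cc$um,
    n_input = tabulate(mi, length(cc$um)),
    n_removed = tabulate(mi[!keep], length(cc$um)))

  out <- .subset_frame(gaze, keep)
  attr(out, "cell_codes") <- list(gid = cc$gid[keep], up = cc$up,
                                  um = cc$um, ut = cc$ut)
  attr(out, "timestamp_trimmed") <- TRUE
  report <- list(n_input = n_in, n_removed = n_in - nrow(out),
                 fraction_removed = (n_in - nrow(out)) / max(n_in, 1L),
                 by_modality = by_mode)
  list(samples = out, report = report)
}

#' Trim behavioral trials by accuracy and reaction time
#'
#' Two-step rule: (1) drop all inaccurate trials; (2) within each
#' participant-session (a participant x modality visit), drop remaining
#' trials whose RT lies more than two sample standard deviations from that
#' session's mean RT. Sessions with zero RT SD, or fewer than 3 accurate
#' trials, skip step 2. Accuracy analyses use the untrimmed table; this trim
#' is for RT and gaze-linked analyses.
#'
#' @param trials trial table with `accurate`, `rt_ms`, `participant_id`,
#'   and a `session` column (defaults to participant x modality if absent).
#' @return list with `trials` (retained rows, provenance-flagged
#'   `rt_trimmed`) and `report` (counts and fractions removed at each step).
#' @export
trim_rts <- function(trials) {
  .assert_untrimmed(trials, "rt_trimmed")
  tt <- as.data.table(trials)
  if (!"session" %in% names(tt))
    tt[, session := paste(participant_id, modality, sep = ":")]
  n_in <- nrow(tt)
  acc <- tt[accurate == TRUE]
  n_inacc <- n_in - nrow(acc)
  exhausted <- setdiff(unique(tt$participant_id), unique(acc$participant_id))
  if (length(exhausted))
    warning("all trials removed for participant(s): ",
            paste(exhausted, collapse = ", "))
  acc[, keep := {
    if (.N < 3L) rep(TRUE, .N) else {
      s <- sd(rt_ms)
      if (!is.finite(s) || s == 0) rep(TRUE, .N) else
        abs(rt_ms - mean(rt_ms)) <= 2 * s
    }
  }, by = session]
  out <- acc[keep == TRUE][, keep := NULL]
  n_outlier <- nrow(acc) - nrow(out)
  setDF(out)
  attr(out, "rt_trimmed") <- TRUE
  report <- list(n_input = n_in, n_inaccurate = n_inacc,
                 n_rt_outlier = n_outlier,
                 n_removed = n_inacc + n_outlier,
                 fraction_removed = (n_inacc + n_outlier) / max(n_in, 1L))
  list(trials = out, report = report)
}

#' Bin labeled gaze samples into target-proportion cells
#'
#' Aggregates labeled gaze samples into half-open time bins
#' `[k * width, (k + 1) * width)` over the analysis window and computes, per
#' participant x modality x trial x bin, the proportion of samples on the
#' target picture out of all samples on either picture. Samples labeled
#' `none` are excluded from the denominator by default (they were discarded
#' at labeling); set `include_none = TRUE` to count them in the denominator
#' instead. Bins with no target/foil samples are absent from the output.
#' `rel_bin` re-indexes bins relative to the trial's disambiguation bin.
#'
#' @param gaze labeled (and normally timestamp-trimmed) gaze table.
#' @param trials trial table supplying `disamb_ms`, `group`, `structure`,
#'   `target_side` per participant x modality x trial.
#' @param window `c(start, end)` analysis window in ms; default 0-12000.
#' @param width bin width in ms; must divide the window; default 100.
#' @param include_none count `none`-labeled samples in the denominator.
#' @return `data.frame` of bin cells: `participant_id`, `group`, `modality`,
#'   `trial_id`, `structure`, `bin_index`, `rel_bin`, `n_target`, `n_foil`,
#'   `n_obs`, `proportion`, and `bin_f` (bin as a factor over the full grid,
#'   for omnibus models).
#' @export
bin_gaze <- function(gaze, trials, window = c(0, 12000), width = 100,
                     include_none = FALSE) {
  span <- window[2] - window[1]
  if (span <= 0 || width <= 0 || abs(span / width - round(span / width)) > 1e-9)
    stop("bin width must positively divide the analysis window")
  n_bins <- as.integer(round(span / width))

  if (!"aoi_label" %in% names(gaze) || anyNA(gaze$aoi_label))
    stop("gaze samples must be labeled (run label_stream first)")
  cc <- .codes_of(gaze)
  lab <- as.character(gaze$aoi_label)
  w <- gaze$timestamp_ms >= window[1] & gaze$timestamp_ms < window[2]
  if (!include_none) w <- w & lab != "none"
  gidw <- cc$gid[w]
  binw <- as.integer((gaze$timestamp_ms[w] - window[1]) %/% width)
  labw <- lab[w]
  # dense cell code over (trial cell, bin); count with tabulate
  code <- (gidw - 1L) * n_bins + binw + 1L
  m <- length(cc$up) * length(cc$um) * length(cc$ut) * n_bins
  n_all <- tabulate(code, m)
  n_tgt <- tabulate(code[labw == "target"], m)
  n_fol <- tabulate(code[labw == "foil"], m)
  occ <- which(n_all >= 1L)
  gid_occ <- (occ - 1L) %/% n_bins + 1L
  ids <- .decode_gid(gid_occ, cc)
  cells <- data.table(
    participant_id = ids$participant_id, modality = ids$modality,
    trial_id = ids$trial_id,
    bin_index = (occ - 1L) %% n_bins,
    n_target = n_tgt[occ], n_foil = n_fol[occ], n_obs = n_all[occ])
  cells[, proportion := n_target / n_obs]

  meta_cols <- intersect(c("participant_id", "modality", "trial_id", "group",
                           "structure", "target_side", "disamb_ms"),
                         names(trials))
  meta <- unique(as.data.table(trials)[, ..meta_cols])
  cells <- merge(cells, meta,
                 by = intersect(c("participant_id", "modality", "trial_id"),
                                meta_cols),
                 all.x = TRUE, sort = FALSE)
  if ("disamb_ms" %in% names(cells))
    cells[, rel_bin := bin_index - as.integer(floor(disamb_ms / width))]
  cells[, bin_f := factor(bin_index, levels = 0:(n_bins - 1L))]
  setorder(cells, participant_id, modality, trial_id, bin_index)
  setDF(cells)
  attr(cells, "window") <- window
  attr(cells, "width") <- width
  cells
}

#' Square-root transform reaction times
#'
#' Adds `sqrt_rt = sqrt(rt_ms)` alongside the original column; RTs are
#' square-root transformed before linear modeling to reduce right skew.
#'
#' @param trials trial table with positive `rt_ms`.
#' @return the table with an added `sqrt_rt` column.
#' @export
transform_rt <- function(trials) {
  if (any(!is.finite(trials$rt_ms) | trials$rt_ms <= 0))
    stop("rt_ms must be strictly positive and finite")
  trials$sqrt_rt <- sqrt(trials$rt_ms)
  trials
}
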