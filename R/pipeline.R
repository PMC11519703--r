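# End-to-end orchestration: simulate (or read) -> label -> trim -> bin ->
# models -> delta -> report. Every stage writes its table under the output
# directory; a manifest records the config hash, seed, per-stage row counts,
# and trim percentages, so identical configs yield identical manifests.

#' Configuration for a full pipeline run
#'
#' Either simulate a study (`sim` is a [sim_config()]) or read existing
#' tables (`gaze_path`, `trials_path`, `viewports_path`).
#'
#' @param sim a [sim_config()], or `NULL` to read input files.
#' @param gaze_path,trials_path,viewports_path input tables (ignored when
#'   `sim` is given).
#' @param out_dir output directory.
#' @param bin_width_ms bin width (ms); default 100.
#' @param window_ms `c(start, end)` analysis window (ms); default 0-12000.
#' @param trim_timestamps,trim_rt stage switches.
#' @param include_none count unassigned samples in proportion denominators.
#' @param fit_models fit accuracy / RT / per-bin proportion models (can be
#'   disabled for data-only runs).
#' @param lag_method `"xcorr"`, `"peak"`, or `"dip"`.
#' @param write_gaze also write the (possibly large) raw and labeled gaze
#'   tables.
#' @param seed seed recorded in the manifest (the simulation seed comes
#'   from `sim$seed`).
#' @param verbose print stage progress.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), gaze_path = NULL,
                       trials_path = NULL, viewports_path = NULL,
                       out_dir = tempfile("gazepipe_run_"),
                       bin_width_ms = 100, window_ms = c(0, 12000),
                       trim_timestamps = TRUE, trim_rt = TRUE,
                       include_none = FALSE, fit_models = TRUE,
                       lag_method = c("xcorr", "peak", "dip"),
                       write_gaze = TRUE,
                       seed = if (!is.null(sim)) sim$seed else 1L,
                       verbose = FALSE) {
  lag_method <- match.arg(lag_method)
  if (is.null(sim)) {
    for (p in c(gaze_path, trials_path))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or nonexistent: ", p %||% "(unset)")
  }
  if (bin_width_ms <= 0 || diff(window_ms) <= 0)
    stop("bin width and window must be positive")
  out <- list(sim = sim, gaze_path = gaze_path, trials_path = trials_path,
              viewports_path = viewports_path, out_dir = out_dir,
              bin_width_ms = bin_width_ms, window_ms = window_ms,
              trim_timestamps = trim_timestamps, trim_rt = trim_rt,
              include_none = include_none, fit_models = fit_models,
              lag_method = lag_method, write_gaze = write_gaze,
              seed = as.integer(seed), verbose = verbose)
  class(out) <- "run_config"
  out
}

.stage <- function(name, log, verbose, expr) {
  msg <- sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name)
  if (verbose) message(msg)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> label -> trim -> bin -> models -> delta
#' -> report, writing every intermediate table (comma-separated text), a
#' run log with trim percentages, and a manifest (config hash, seed, stage
#' row counts). Identical configurations produce identical manifests.
#'
#' @param config a [run_config()].
#' @return the manifest (named list), invisibly; also written as
#'   `manifest.yaml` in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stages <- character(0)
  counts <- list()
  v <- config$verbose

  # -- simulate / load ------------------------------------------------------
  if (!is.null(config$sim)) {
    study <- .stage("simulate", log_lines, v, simulate_study(config$sim))
    gaze <- study$gaze; trials <- study$trials; viewports <- study$viewports
    write_table(study$design, file.path(out_dir, "design.csv"))
    note("simulate: %d trial rows, %d gaze samples (seed %d)",
         nrow(trials), nrow(gaze), config$sim$seed)
  } else {
    gaze <- .stage("load", log_lines, v, read_gaze_table(config$gaze_path))
    trials <- .stage("load", log_lines, v,
                     read_trial_table(config$trials_path))
    viewports <- if (!is.null(config$viewports_path))
      .stage("load", log_lines, v,
             read_viewport_table(config$viewports_path)) else NULL
    note("load: %d trial rows, %d gaze samples", nrow(trials), nrow(gaze))
  }
  stages <- c(stages, "simulate")
  counts$trials <- nrow(trials); counts$gaze_samples <- nrow(gaze)
  write_table(trials, file.path(out_dir, "trials.csv"))
  write_table(viewports, file.path(out_dir, "viewports.csv"))
  if (config$write_gaze) write_table(gaze, file.path(out_dir, "gaze.csv"))

  # -- label ----------------------------------------------------------------
  labeled <- .stage("label", log_lines, v,
                    label_stream(gaze, trials, viewports))
  stages <- c(stages, "label")
  counts$labeled <- nrow(labeled)
  note("label: %d samples, %.1f%% outside both AOIs (discarded)",
       nrow(labeled), 100 * mean(labeled$discarded))
  if (config$write_gaze)
    write_table(labeled, file.path(out_dir, "labeled.csv"))

  # -- trim -----------------------------------------------------------------
  if (config$trim_timestamps) {
    tr <- .stage("trim", log_lines, v, trim_timestamps(labeled))
    labeled <- tr$samples
    note("trim: %.1f%% of the eye data removed (timestamp 2-SD rule)",
         100 * tr$report$fraction_removed)
    counts$gaze_after_trim <- nrow(labeled)
  }
  trials_rt <- trials
  if (config$trim_rt) {
    tr <- .stage("trim", log_lines, v, trim_rts(trials))
    trials_rt <- tr$trials
    note("trim: %.1f%% of the RT data removed (%d inaccurate, %d outliers)",
         100 * tr$report$fraction_removed, tr$report$n_inaccurate,
         tr$report$n_rt_outlier)
    counts$trials_after_trim <- nrow(trials_rt)
  }
  stages <- c(stages, "trim")

  # -- bin ------------------------------------------------------------------
  bins <- .stage("bin", log_lines, v,
                 bin_gaze(labeled, trials, window = config$window_ms,
                          width = config$bin_width_ms,
                          include_none = config$include_none))
  stages <- c(stages, "bin")
  counts$bin_cells <- nrow(bins)
  note("bin: %d cells (%g-ms bins over %g-%g ms)", nrow(bins),
       config$bin_width_ms, config$window_ms[1], config$window_ms[2])
  write_table(bins, file.path(out_dir, "bins.csv"))

  # -- models ---------------------------------------------------------------
  if (config$fit_models) {
    acc_fit <- .stage("model", log_lines, v, fit_accuracy(trials))
    rt_fit <- .stage("model", log_lines, v,
                     fit_rt(transform_rt(trials_rt)))
    exp_bins <- bins[bins$structure != "filler", ]
    exp_bins <- complete_bins(exp_bins)
    prop_fit <- .stage("model", log_lines, v,
                       fit_binwise(exp_bins,
                                   proportion ~ bin_f * group * modality))
    gc_con <- binwise_contrasts(prop_fit, "group", c("pwa", "control"))
    write_table(acc_fit$coefficients, file.path(out_dir, "model_accuracy.csv"))
    write_table(rt_fit$coefficients, file.path(out_dir, "model_rt.csv"))
    write_table(prop_fit$coefficients,
                file.path(out_dir, "model_proportions.csv"))
    write_table(gc_con, file.path(out_dir, "contrasts_group.csv"))
    note("model: accuracy n=%d, rt n=%d (R2m=%.3f), proportions n=%d (disp=%.3f)",
         acc_fit$n, rt_fit$n, rt_fit$r2_marginal, prop_fit$n,
         prop_fit$dispersion)
    stages <- c(stages, "model")
  }

  # -- delta ----------------------------------------------------------------
  delta <- .stage("delta", log_lines, v, compute_delta(bins))
  write_table(delta, file.path(out_dir, "delta.csv"))
  pooled <- compute_delta(bins, by_structure = FALSE)
  lag <- .stage("delta", log_lines, v,
                estimate_lag(pooled[pooled$modality == "lab", ],
                             pooled[pooled$modality == "web", ],
                             method = config$lag_method,
                             bin_width_ms = config$bin_width_ms))
  stages <- c(stages, "delta")
  counts$delta_cells <- nrow(delta)
  note("delta: %d cells; %s lag = %d bins (%g ms)", nrow(delta),
       lag$method, lag$lag_bins, lag$lag_ms)

  # -- report ---------------------------------------------------------------
  report <- c(
    "gazepipe run report",
    sprintf("seed: %d", config$seed),
    sprintf("delta peak bin: lab %d, web %d",
            lag$diagnostics$peak_bin_lab, lag$diagnostics$peak_bin_web),
    sprintf("delta dip bin:  lab %d, web %d",
            lag$diagnostics$dip_bin_lab, lag$diagnostics$dip_bin_web),
    sprintf("estimated web-lab lag (%s): %d bins = %g ms",
            lag$method, lag$lag_bins, lag$lag_ms),
    log_lines)
  writeLines(report, file.path(out_dir, "report.txt"))
  stages <- c(stages, "report")

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = stages, row_counts = counts,
                   lag_bins = lag$lag_bins, lag_ms = lag$lag_ms)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}

#' Restrict a bin table to bins with complete design cells
#'
#' Keeps only bins where every group x modality x structure combination
#' present in the table contributed at least one cell, so omnibus models
#' with bin interactions stay estimable.
#'
#' @param bins a bin-cell table from [bin_gaze()].
#' @return the filtered table with `bin_f` levels dropped accordingly.
#' @export
complete_bins <- function(bins) {
  bt <- as.data.table(bins)
  need <- length(unique(bt$group)) * length(unique(bt$modality)) *
    length(unique(bt$structure))
  ok <- bt[, uniqueN(paste(group, modality, structure)), by = bin_index]
  keep_bins <- ok[V1 == need]$bin_index
  out <- bt[bin_index %in% keep_bins]
  out[, bin_f := droplevels(bin_f)]
  setDF(out)
  out
}
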