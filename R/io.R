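# Delimited-text readers and writers for every pipeline table
# (comma-separated, header row, UTF-8), plus config serialization.
# Readers validate mandatory columns and report malformed numeric fields
# with their file line numbers (header = line 1).

.read_table <- function(path, mandatory, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- names(data.table::fread(path, nrows = 0L, showProgress = FALSE))
  cc <- intersect(numeric_cols, hdr)
  dt <- data.table::fread(path,
                          colClasses = if (length(cc)) list(character = cc),
                          encoding = "UTF-8", showProgress = FALSE)
  miss <- setdiff(mandatory, names(dt))
  if (length(miss))
    stop("missing mandatory column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  for (col in intersect(numeric_cols, names(dt))) {
    raw <- dt[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "" & raw != "NA")
    if (length(bad))
      stop("malformed ", col, " in ", basename(path), " at line(s): ",
           paste(bad + 1L, collapse = ", "))
    data.table::set(dt, j = col, value = num)
  }
  setDF(dt)
  dt
}

#' Read a gaze-sample table
#'
#' Comma-separated, header row, UTF-8. Mandatory columns: `participant_id`,
#' `trial_id`, `modality`, `timestamp_ms`; coordinate-mode rows carry
#' `x_px`/`y_px`, label-mode rows `aoi_label`. Unknown columns are
#' preserved. Malformed numeric fields are rejected with their line number.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_gaze_table <- function(path) {
  out <- .read_table(path,
                     mandatory = c("participant_id", "trial_id", "modality",
                                   "timestamp_ms"),
                     numeric_cols = c("timestamp_ms", "x_px", "y_px"))
  if (!any(c("x_px", "aoi_label") %in% names(out)))
    stop("gaze table needs either x_px/y_px or aoi_label columns")
  out
}

#' Read a trial-metadata table
#'
#' Mandatory columns: `participant_id`, `trial_id`, `group`, `modality`,
#' `structure`, `target_side`, `disamb_ms`, `rt_ms`, `accurate`.
#'
#' @param path file path.
#' @return `data.frame` (with `accurate` coerced to logical).
#' @export
read_trial_table <- function(path) {
  out <- .read_table(path,
                     mandatory = c("participant_id", "trial_id", "group",
                                   "modality", "structure", "target_side",
                                   "disamb_ms", "rt_ms", "accurate"),
                     numeric_cols = c("disamb_ms", "rt_ms"))
  out$accurate <- as.logical(out$accurate)
  out
}

#' Read a per-participant viewport table
#'
#' Mandatory columns: `participant_id`, `modality`, `width_px`, `height_px`.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_viewport_table <- function(path) {
  .read_table(path,
              mandatory = c("participant_id", "modality", "width_px",
                            "height_px"),
              numeric_cols = c("width_px", "height_px"))
}

#' Read a bin-cell table written by the pipeline
#'
#' @param path file path.
#' @return `data.frame` with `bin_f` restored as a factor.
#' @export
read_bin_table <- function(path) {
  out <- .read_table(path,
                     mandatory = c("participant_id", "trial_id", "modality",
                                   "bin_index", "n_target", "n_foil",
                                   "proportion"),
                     numeric_cols = c("bin_index", "n_target", "n_foil",
                                      "n_obs", "proportion", "rel_bin",
                                      "disamb_ms"))
  if ("bin_f" %in% names(out)) out$bin_f <- factor(out$bin_f)
  out
}

#' Write a pipeline table as comma-separated text
#'
#' @param x data.frame.
#' @param path destination path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' Serialize / restore a simulation or run configuration
#'
#' Configurations round-trip through a structured key-value (YAML) file;
#' [config_hash()] gives a stable digest of the serialized form for run
#' manifests.
#'
#' @param config a [sim_config()] or [run_config()].
#' @param path destination / source path.
#' @return `write_config`: the path, invisibly; `read_config`: the restored
#'   object.
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  obj <- unclass(config)
  obj$.class <- class(config)[1]
  if (!is.null(obj$sim)) obj$sim <- unclass(obj$sim)
  # yaml drops names on atomic vectors; carry them as maps instead
  yamlify <- function(x) {
    if (is.data.frame(x)) as.list(x)
    else if (is.list(x)) lapply(x, yamlify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(obj), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class %||% "sim_config"
  obj$.class <- NULL
  restore_named <- function(x) if (is.list(x) && !is.data.frame(x) &&
                                     length(x) && !is.null(names(x)) &&
                                     all(vapply(x, is.numeric, TRUE)) &&
                                     all(lengths(x) == 1L))
    unlist(x) else x
  fix_cfg <- function(cfg) {
    for (nm in c("ramp_onset_delay_ms", "ramp_rate", "rt_meanlog_group",
                 "rt_meanlog_structure", "rt_meanlog_mode",
                 "spatial_noise_px", "dropout_prob"))
      cfg[[nm]] <- restore_named(cfg[[nm]])
    for (nm in c("asymptote", "accuracy_logit"))
      cfg[[nm]] <- lapply(cfg[[nm]], restore_named)
    cfg$web_viewports <- as.data.frame(cfg$web_viewports)
    cfg
  }
  if (cls == "sim_config") {
    cfg <- fix_cfg(obj)
    class(cfg) <- "sim_config"
    validate_sim_config(cfg)
    return(cfg)
  }
  if (!is.null(obj$sim)) {
    obj$sim <- fix_cfg(obj$sim)
    class(obj$sim) <- "sim_config"
  }
  class(obj) <- cls
  obj
}

#' @rdname write_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
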