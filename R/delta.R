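# Delta-gaze: the per-bin control-minus-pwa difference in mean target-gaze
# proportion, computed separately per structure type and modality, and the
# lag analysis comparing where the lab and web difference series peak, dip,
# and maximally cross-correlate.

#' Compute the control-minus-pwa difference series
#'
#' For each bin x structure x modality cell, subtracts the aphasia group's
#' mean target-gaze proportion from the control group's mean (trial-level
#' proportions weighted equally by default; set
#' `participant_mean_first = TRUE` to average within participants before
#' averaging across them). Cells where either group contributed no data are
#' omitted (count reported in `attr(, "n_omitted")`). Filler trials are
#' excluded by default.
#'
#' @param bins a bin-cell table from [bin_gaze()] with `group`, `structure`,
#'   `modality`, `bin_index`, `proportion`.
#' @param by_structure keep structure types separate (default) or pool them
#'   into a single `"all"` series.
#' @param structures structure types to include.
#' @param participant_mean_first average proportions within participants
#'   before the group mean.
#' @return `data.frame`: `bin_index`, `structure`, `modality`, `delta`,
#'   `n_control_cells`, `n_pwa_cells`.
#' @export
compute_delta <- function(bins, by_structure = TRUE,
                          structures = c("active", "passive", "locative"),
                          participant_mean_first = FALSE) {
  bt <- as.data.table(bins)
  bt <- bt[structure %in% structures]
  for (md in unique(bt$modality))
    if (length(unique(bt[modality == md]$group)) < 2L)
      stop("modality '", md, "' is missing one of the groups entirely")
  if (!by_structure) bt[, structure := "all"]

  if (participant_mean_first) {
    bt <- bt[, .(proportion = mean(proportion), n_cells = .N),
             by = .(group, modality, structure, bin_index, participant_id)]
    grp <- bt[, .(m = mean(proportion), n = .N),
              by = .(group, modality, structure, bin_index)]
  } else {
    grp <- bt[, .(m = mean(proportion), n = .N),
              by = .(group, modality, structure, bin_index)]
  }
  wide <- data.table::dcast(grp, modality + structure + bin_index ~ group,
                            value.var = c("m", "n"))
  complete <- !is.na(wide$m_control) & !is.na(wide$m_pwa)
  n_omitted <- sum(!complete)
  wide <- wide[complete]
  out <- data.frame(bin_index = wide$bin_index, structure = wide$structure,
                    modality = wide$modality,
                    delta = wide$m_control - wide$m_pwa,
                    n_control_cells = wide$n_control,
                    n_pwa_cells = wide$n_pwa, stringsAsFactors = FALSE)
  out <- out[order(out$modality, out$structure, out$bin_index), ]
  rownames(out) <- NULL
  attr(out, "n_omitted") <- n_omitted
  out
}

#' Model the delta-gaze series against bin and modality
#'
#' Linear regression of the difference series on bin number (numeric),
#' modality, and their interaction, without random effects (the series is
#' already an average). A positive bin-by-web interaction indicates that
#' the group difference persists later on the web than in the lab.
#'
#' @param series a [compute_delta()] result.
#' @return a `gp_fit` (family `gaussian`); the `lm` object is in `$model`.
#' @export
fit_delta_model <- function(series) {
  for (md in unique(series$modality))
    if (length(unique(series$bin_index[series$modality == md])) < 2L)
      stop("need at least 2 bins per modality")
  if (var(series$delta) == 0)
    warning("constant delta series; slopes are zero by construction")
  series$modality <- factor(series$modality)
  model <- lm(delta ~ bin_index * modality, data = series)
  sm <- summary(model)$coefficients
  cf <- .coef_table(sm[, 1], sm[, 2], rep(model$df.residual, nrow(sm)))
  .new_fit(cf, family = "gaussian", n = nrow(series), model = model,
           converged = TRUE, formula = delta ~ bin_index * modality)
}

.as_series <- function(x) {
  if (is.data.frame(x)) {
    dt <- as.data.table(x)[, .(delta = mean(delta)), by = bin_index]
    setorder(dt, bin_index)
    setNames(dt$delta, dt$bin_index)
  } else {
    if (is.null(names(x))) names(x) <- seq_along(x) - 1L
    x[order(as.integer(names(x)))]
  }
}

.fill_series <- function(s) {
  bins <- as.integer(names(s))
  grid <- seq(min(bins), max(bins))
  if (length(grid) == length(bins)) return(setNames(as.numeric(s), grid))
  setNames(approx(bins, as.numeric(s), xout = grid)$y, grid)
}

.moving_average <- function(v, k = 3L) {
  half <- k %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Estimate the web-versus-lab temporal lag of a difference series
#'
#' Compares where the lab and web delta-gaze series peak (`method =
#' "peak"`), dip (`"dip"`), or align best under a shift (`"xcorr"`,
#' normalized cross-correlation over a bounded lag search window). Both
#' series are linearly interpolated onto their full bin grid first; ties go
#' to the earliest bin (peak/dip) or the smallest-magnitude lag (xcorr).
#' Positive lags mean the web series trails the lab series.
#'
#' @param lab,web delta series for one modality each: a [compute_delta()]
#'   subset (data.frame) or a numeric vector named by bin index.
#' @param method `"xcorr"` (default), `"peak"`, or `"dip"`.
#' @param max_lag_bins half-width of the xcorr lag search window (bins).
#' @param smooth apply a centered 3-bin moving average before locating
#'   peaks/dips.
#' @param bin_width_ms bin width used to convert bins to ms.
#' @return object of class `lag_estimate`: `method`, `lag_bins`, `lag_ms`,
#'   and `diagnostics` (peak/dip bins per series; the correlation profile
#'   for xcorr).
#' @export
estimate_lag <- function(lab, web, method = c("xcorr", "peak", "dip"),
                         max_lag_bins = 20L, smooth = FALSE,
                         bin_width_ms = 100) {
  method <- match.arg(method)
  s_lab <- .fill_series(.as_series(lab))
  s_web <- .fill_series(.as_series(web))
  if (length(s_lab) < 5L || length(s_web) < 5L)
    stop("series too short: need at least 5 bins per modality")
  if (smooth) {
    s_lab[] <- .moving_average(s_lab)
    s_web[] <- .moving_average(s_web)
  }
  bins_lab <- as.integer(names(s_lab))
  bins_web <- as.integer(names(s_web))

  diag <- list(
    peak_bin_lab = bins_lab[which.max(s_lab)],
    peak_bin_web = bins_web[which.max(s_web)],
    dip_bin_lab = bins_lab[which.min(s_lab)],
    dip_bin_web = bins_web[which.min(s_web)])

  if (method == "peak") {
    lag <- diag$peak_bin_web - diag$peak_bin_lab
  } else if (method == "dip") {
    lag <- diag$dip_bin_web - diag$dip_bin_lab
  } else {
    common <- intersect(bins_lab, bins_web)
    a <- s_lab[as.character(common)]
    b <- s_web[as.character(common)]
    ks <- seq(-max_lag_bins, max_lag_bins)
    prof <- vapply(ks, function(k) {
      # web(t) ~ lab(t - k): correlate lab[i] with web[i + k]
      i <- seq_along(common)
      j <- i + k
      ok <- j >= 1L & j <= length(common)
      if (sum(ok) < 5L) return(NA_real_)
      suppressWarnings(cor(a[i[ok]], b[j[ok]]))
    }, numeric(1))
    best <- max(prof, na.rm = TRUE)
    cand <- ks[which(!is.na(prof) & prof >= best - 1e-12)]
    lag <- cand[which.min(abs(cand))]
    diag$xcorr_profile <- data.frame(lag_bins = ks, correlation = prof)
  }
  if (abs(lag) > max(length(s_lab), length(s_web)))
    stop("estimated lag exceeds series length")
  out <- list(method = method, lag_bins = as.integer(lag),
              lag_ms = lag * bin_width_ms, diagnostics = diag)
  class(out) <- "lag_estimate"
  out
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> method = %s: lag = %d bins (%g ms)\n",
              x$method, x$lag_bins, x$lag_ms))
  cat(sprintf("  peaks: lab bin %d, web bin %d; dips: lab bin %d, web bin %d\n",
              x$diagnostics$peak_bin_lab, x$diagnostics$peak_bin_web,
              x$diagnostics$dip_bin_lab, x$diagnostics$dip_bin_web))
  invisible(x)
}
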