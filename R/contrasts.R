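# Bin-wise marginal contrasts from an omnibus proportion fit.
#
# For every level b of the bin factor, the engine builds the reference grid
# of all remaining factors, averages model-matrix rows with equal weights
# (equal-weight marginal means), and forms the link-scale difference between
# the two requested levels of the contrast factor — or, when `within` is
# given, the difference of those differences across two levels of a third
# factor (e.g. the group difference on the web minus the group difference in
# the lab). Tests use the fit's residual df with dispersion-scaled SEs.

.grid_row <- function(fit, values) {
  tm <- delete.response(fit$terms)
  vars <- all.vars(tm)
  grid_vars <- lapply(vars, function(v) {
    if (v %in% names(fit$xlevels)) {
      if (v %in% names(values)) values[[v]] else fit$xlevels[[v]]
    } else {
      if (v %in% names(values)) values[[v]] else unname(fit$num_means[[v]])
    }
  })
  names(grid_vars) <- vars
  grid <- expand.grid(grid_vars, stringsAsFactors = FALSE)
  for (v in names(fit$xlevels))
    grid[[v]] <- factor(grid[[v]], levels = fit$xlevels[[v]])
  mm <- model.matrix(tm, grid, contrasts.arg = fit$contrasts)
  colMeans(mm)
}

.contrast_vector <- function(fit, factor_name, levels, fixed = list()) {
  v1 <- .grid_row(fit, c(fixed, setNames(list(levels[1]), factor_name)))
  v2 <- .grid_row(fit, c(fixed, setNames(list(levels[2]), factor_name)))
  v1 - v2
}

#' Per-bin contrasts from an omnibus proportion model
#'
#' Extracts, for every bin level in the fit, the marginal link-scale
#' difference between two levels of a factor (e.g. `pwa - control`), or the
#' modality-by-group interaction contrast when `within` is supplied
#' (difference of group differences between two modality levels). Marginal
#' means average the remaining factors with equal weights. Contiguous runs
#' of significant bins are summarized as windows in
#' `attr(result, "windows")`.
#'
#' @param fit a quasibinomial `gp_fit` from [fit_binwise()] whose model
#'   includes a bin factor interacting with the contrast factor.
#' @param factor name of the factor to contrast (e.g. `"group"`).
#' @param levels length-2 character: contrast is `levels[1] - levels[2]`.
#' @param by name of the bin factor column; default `"bin_f"`.
#' @param within optional list `list(var =, levels = c(hi, lo))` requesting
#'   the difference of the factor contrast between two levels of `var`.
#' @param alpha significance threshold for window summaries.
#' @param adjust multiplicity adjustment across bins (see
#'   [stats::p.adjust()]); `"none"` by default, matching per-bin reporting
#'   without correction.
#' @return `data.frame` with one row per bin: `bin`, `contrast`, `estimate`,
#'   `se`, `statistic`, `p`, `significant`; attributes `windows` (onset /
#'   offset / sign of each significant run) and `contrast_matrix`.
#' @export
binwise_contrasts <- function(fit, factor = "group",
                              levels = c("pwa", "control"), by = "bin_f",
                              within = NULL, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(fit, "gp_fit"))
  if (!factor %in% names(fit$xlevels))
    stop("contrast not estimable: no '", factor, "' factor in the model")
  if (!all(levels %in% fit$xlevels[[factor]]))
    stop("contrast not estimable: missing level(s) ",
         paste(setdiff(levels, fit$xlevels[[factor]]), collapse = ", "))
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  # a model without the bin factor is treated as a single implicit bin
  one_bin <- !by %in% names(fit$xlevels)
  bins <- if (one_bin) "0" else fit$xlevels[[by]]

  cmat <- vapply(bins, function(b) {
    fixed <- if (one_bin) list() else setNames(list(b), by)
    if (is.null(within)) {
      .contrast_vector(fit, factor, levels, fixed)
    } else {
      hi <- .contrast_vector(fit, factor, levels,
                             c(fixed, setNames(list(within$levels[1]),
                                               within$var)))
      lo <- .contrast_vector(fit, factor, levels,
                             c(fixed, setNames(list(within$levels[2]),
                                               within$var)))
      hi - lo
    }
  }, numeric(length(beta)))

  est <- drop(crossprod(cmat, beta))
  se <- sqrt(colSums(cmat * (fit$vcov %*% cmat)))
  df <- fit$df_residual %||% Inf
  stat <- est / se
  p <- if (is.infinite(df)) 2 * pnorm(-abs(stat)) else 2 * pt(-abs(stat), df)
  p <- stats::p.adjust(p, method = adjust)

  lab <- paste(levels[1], "-", levels[2])
  if (!is.null(within))
    lab <- sprintf("(%s | %s=%s) - (%s | %s=%s)", lab, within$var,
                   within$levels[1], lab, within$var, within$levels[2])
  out <- data.frame(bin = as.integer(as.character(bins)), contrast = lab,
                    estimate = est, se = se, statistic = stat, p = p,
                    significant = p < alpha, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$bin), ]
  attr(out, "windows") <- significant_runs(out)
  attr(out, "contrast_matrix") <- cmat
  attr(out, "alpha") <- alpha
  out
}

#' Summarize contiguous significant bins as windows
#'
#' Groups consecutive significant bins of the same sign into windows
#' (onset bin, offset bin), the way divergence onsets are narrated in
#' time-course analyses.
#'
#' @param contrasts a [binwise_contrasts()] result (or any data.frame with
#'   `bin`, `estimate`, `significant`).
#' @return `data.frame` with `onset_bin`, `offset_bin`, `sign`, `n_bins`.
#' @export
significant_runs <- function(contrasts) {
  sig <- contrasts[contrasts$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(onset_bin = integer(0), offset_bin = integer(0),
                      sign = integer(0), n_bins = integer(0)))
  sig <- sig[order(sig$bin), ]
  sgn <- sign(sig$estimate)
  new_run <- c(TRUE, diff(sig$bin) != 1 | diff(sgn) != 0)
  run_id <- cumsum(new_run)
  do.call(rbind, lapply(split(seq_len(nrow(sig)), run_id), function(i)
    data.frame(onset_bin = min(sig$bin[i]), offset_bin = max(sig$bin[i]),
               sign = sgn[i[1]], n_bins = length(i))))
}

#' Marginal contrast as a weighted average of per-bin contrasts
#'
#' Collapses the per-bin contrast series into a single marginal effect by
#' averaging the bin-wise contrast vectors with the supplied weights
#' (typically bin frequencies), then testing the combined linear
#' combination against the fit's covariance.
#'
#' @param fit the `gp_fit` the contrasts came from.
#' @param contrasts a [binwise_contrasts()] result.
#' @param weights per-bin weights (recycled; default equal).
#' @return one-row `data.frame` with `estimate`, `se`, `statistic`, `p`.
#' @export
marginal_contrast <- function(fit, contrasts, weights = NULL) {
  cmat <- attr(contrasts, "contrast_matrix")
  if (is.null(cmat)) stop("contrasts must come from binwise_contrasts()")
  w <- if (is.null(weights)) rep(1, ncol(cmat)) else rep_len(weights, ncol(cmat))
  cvec <- drop(cmat %*% (w / sum(w)))
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  est <- sum(cvec * beta)
  se <- sqrt(drop(crossprod(cvec, fit$vcov %*% cvec)))
  df <- fit$df_residual %||% Inf
  stat <- est / se
  p <- if (is.infinite(df)) 2 * pnorm(-abs(stat)) else 2 * pt(-abs(stat), df)
  data.frame(estimate = est, se = se, statistic = stat, p = p)
}
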