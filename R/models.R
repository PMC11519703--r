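# Model families:
#  * accuracy: binomial mixed logistic (participant + trial random intercepts),
#    delegated to lme4, with a fixed-effects fallback on non-convergence;
#  * reaction time: gaussian mixed model on sqrt(RT), delegated to lmerTest
#    for Satterthwaite df;
#  * per-bin gaze proportions: weighted quasibinomial logit fit by an
#    in-package IRLS with Pearson-dispersion-scaled standard errors (random
#    effects are deliberately not supported for this family).
# The IRLS solves on covariate-aggregated cells (same MLE, since the binomial
# log-likelihood depends on covariate-identical rows only through their
# weighted totals) and computes the Pearson dispersion on the original rows.

#' Specify a proportion/behavioral model
#'
#' Small container validating a model request before fitting: formula,
#' family, optional random-intercept factors, and the weights source.
#' The quasibinomial family forbids random effects.
#'
#' @param formula model formula (`response ~ fixed terms`).
#' @param family `"quasibinomial"`, `"binomial-mixed"`, or
#'   `"gaussian-mixed"`.
#' @param random character vector of random-intercept grouping columns
#'   (empty or `NULL` for none).
#' @param weights column name holding per-row binomial totals (quasibinomial
#'   only), `"none"` for unweighted, or `NULL` for the default `n_obs`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(formula,
                       family = c("quasibinomial", "binomial-mixed",
                                  "gaussian-mixed"),
                       random = NULL, weights = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(formula, "formula"))
  if (family == "quasibinomial" && length(random))
    stop("quasibinomial models do not support random effects")
  out <- list(formula = formula, family = family, random = random,
              weights = weights)
  class(out) <- "model_spec"
  out
}

.coef_table <- function(est, se, df, stat_name = "t") {
  stat <- est / se
  df_ok <- ifelse(is.finite(df) & df <= 0, NA_real_, df)  # saturated fits
  p <- ifelse(is.infinite(df_ok), 2 * pnorm(-abs(stat)),
              suppressWarnings(2 * pt(-abs(stat), df_ok)))
  crit <- ifelse(is.infinite(df_ok), qnorm(0.975),
                 suppressWarnings(qt(0.975, df_ok)))
  # approximate standardized effect size from the test statistic
  d <- 2 * stat /
    sqrt(ifelse(is.infinite(df_ok), pmax(1, length(est)), df_ok))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             df = unname(df), statistic = unname(stat), p = unname(p),
             d = unname(d),
             ci_lower = unname(est - crit * se),
             ci_upper = unname(est + crit * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

.new_fit <- function(coefs, family, n, ...) {
  out <- c(list(coefficients = coefs, family = family, n = n), list(...))
  class(out) <- "gp_fit"
  out
}

#' @export
print.gp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<gp_fit> %s, n = %d%s\n", x$family, x$n,
              if (!is.null(x$dispersion))
                sprintf(", dispersion = %.4g", x$dispersion) else ""))
  if (!is.null(x$converged) && !x$converged)
    cat("  (did not converge)\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Fit the quasibinomial per-bin gaze-proportion model
#'
#' Fits a logit-link proportion regression by iteratively reweighted least
#' squares, with per-cell binomial totals as prior weights and a dispersion
#' parameter estimated as Pearson chi-square over residual degrees of
#' freedom; all standard errors are scaled by the square root of the
#' dispersion. Bin typically enters as a categorical factor (`bin_f` from
#' [bin_gaze()]) interacting with group / structure / modality, giving the
#' omnibus model whose per-bin contrasts [binwise_contrasts()] extracts.
#' Unused factor levels are dropped; inestimable terms (empty design cells)
#' raise an error naming the offending columns.
#'
#' @param data a bin-cell table from [bin_gaze()] (or any data.frame with a
#'   proportion response in `[0, 1]`).
#' @param spec a [model_spec()] or a bare formula (then treated as
#'   quasibinomial, weighted by `n_obs` when present).
#' @param tol relative deviance convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @return a `gp_fit` with coefficient table, scaled `vcov`, `dispersion`,
#'   residual df, and the metadata needed by [binwise_contrasts()].
#' @export
fit_binwise <- function(data, spec = proportion ~ bin_f * group,
                        tol = 1e-12, max_iter = 100L) {
  if (inherits(spec, "formula")) spec <- model_spec(spec, "quasibinomial")
  stopifnot(inherits(spec, "model_spec"), spec$family == "quasibinomial")
  formula <- spec$formula

  mf <- model.frame(formula, data, drop.unused.levels = TRUE)
  y <- model.response(mf)
  if (any(y < 0 | y > 1)) stop("response must be a proportion in [0, 1]")
  w <- if (identical(spec$weights, "none")) rep(1, nrow(mf))
       else if (!is.null(spec$weights)) as.numeric(data[[spec$weights]])
       else if ("n_obs" %in% names(data)) as.numeric(data[["n_obs"]])
       else rep(1, nrow(mf))
  if (length(w) != nrow(mf) || any(w <= 0)) stop("invalid weights")
  X <- model.matrix(formula, mf)

  # aggregate covariate-identical rows: identical MLE, much smaller solve
  key <- do.call(paste, c(mf[-1L], list(sep = "\r")))
  g <- match(key, unique(key))
  first <- which(!duplicated(g))
  Xa <- X[first, , drop = FALSE]
  wa <- as.vector(tapply(w, g, sum))
  ya <- as.vector(tapply(w * y, g, sum)) / wa

  qx <- qr(Xa * sqrt(wa))
  if (qx$rank < ncol(Xa)) {
    bad <- colnames(Xa)[qx$pivot[(qx$rank + 1L):ncol(Xa)]]
    stop("inestimable terms (empty design cells): ",
         paste(bad, collapse = ", "))
  }

  eps <- 1e-10
  mu <- (wa * ya + 0.5) / (wa + 1)
  eta <- qlogis(mu)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- pmin(pmax(plogis(eta), eps), 1 - eps)
    vmu <- mu * (1 - mu)
    z <- eta + (ya - mu) / vmu
    fit <- lm.wfit(Xa, z, wa * vmu)
    beta <- fit$coefficients
    eta <- drop(Xa %*% beta)
    mu <- pmin(pmax(plogis(eta), eps), 1 - eps)
    dev <- -2 * sum(wa * (ya * log(mu) + (1 - ya) * log(1 - mu)))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }

  vmu <- mu * (1 - mu)
  xtwx <- crossprod(Xa * sqrt(wa * vmu))
  vcov_u <- chol2inv(chol(xtwx))
  dimnames(vcov_u) <- list(colnames(Xa), colnames(Xa))

  # Pearson dispersion on the original (unaggregated) rows
  mu_orig <- mu[g]
  df_resid <- nrow(mf) - ncol(Xa)
  pearson <- sum(w * (y - mu_orig)^2 / (mu_orig * (1 - mu_orig)))
  dispersion <- if (df_resid > 0) pearson / df_resid else NA_real_
  vc <- vcov_u * dispersion
  se <- sqrt(diag(vc))

  num_means <- vapply(mf[-1L], function(col)
    if (is.numeric(col)) mean(col) else NA_real_, numeric(1))

  .new_fit(.coef_table(beta, se, rep(df_resid, length(beta))),
           family = "quasibinomial", n = nrow(mf),
           vcov = vc, dispersion = dispersion, df_residual = df_resid,
           deviance = dev, converged = converged, iterations = it,
           formula = formula, terms = terms(mf),
           xlevels = .getXlevels(terms(mf), mf),
           contrasts = attr(X, "contrasts"), num_means = num_means)
}

#' Fit the accuracy model (binomial mixed logistic)
#'
#' Logistic regression of response accuracy on structure type and modality
#' with participant and trial (item) random intercepts, intended for the
#' aphasia group only (controls respond at ceiling, leaving no variance to
#' model). Accuracy is analyzed untrimmed. If the mixed fit fails to
#' converge, the function falls back to a fixed-effects logistic fit with a
#' warning.
#'
#' @param trials untrimmed trial table; rows with `group != "pwa"` and
#'   filler trials are dropped (with a message) unless already absent.
#' @param formula fixed-effects formula; default
#'   `accurate ~ structure + modality`.
#' @param random use participant + trial random intercepts.
#' @return a `gp_fit` (family `binomial-mixed`); the underlying model object
#'   is in `$model`.
#' @export
fit_accuracy <- function(trials, formula = accurate ~ structure + modality,
                         random = TRUE) {
  tt <- trials
  if ("group" %in% names(tt) && any(tt$group != "pwa")) {
    message("fit_accuracy: dropping non-pwa rows (controls are at ceiling)")
    tt <- tt[tt$group == "pwa", ]
  }
  if ("structure" %in% names(tt) && any(tt$structure == "filler"))
    tt <- tt[tt$structure != "filler", ]
  tt <- droplevels(tt)
  if (length(unique(tt$accurate)) < 2L)
    stop("degenerate response: accuracy has a single level")

  if (random) {
    mixed_formula <- update(formula,
                            . ~ . + (1 | participant_id) + (1 | trial_id))
    model <- tryCatch({
      fit <- lme4::glmer(mixed_formula, data = tt, family = binomial())
      conv <- fit@optinfo$conv$lme4
      if (!is.null(conv$code) && conv$code != 0) stop("non-convergence")
      fit
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(model)) {
      warning("mixed accuracy model did not converge; ",
              "falling back to fixed-effects logistic")
      model <- stats::glm(formula, data = tt, family = binomial())
    }
  } else {
    model <- stats::glm(formula, data = tt, family = binomial())
  }

  if (inherits(model, "merMod")) {
    sm <- summary(model)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  } else {
    sm <- summary(model)$coefficients
    est <- sm[, 1]; se <- sm[, 2]
  }
  df <- rep(Inf, length(est))
  cf <- .coef_table(est, se, df)
  # z-based approximate d with residual df in the denominator
  cf$d <- 2 * cf$statistic / sqrt(max(nrow(tt) - length(est), 1))
  .new_fit(cf, family = "binomial-mixed", n = nrow(tt), model = model,
           converged = TRUE, formula = formula)
}

#' Fit the reaction-time model (gaussian mixed)
#'
#' Linear mixed model of square-root-transformed RT on group, structure
#' type, and modality (full factorial by default) with participant and trial
#' random intercepts; degrees of freedom and p-values use the Satterthwaite
#' approximation. Expects an RT-trimmed, [transform_rt()]-processed table
#' (warns otherwise). Marginal and conditional variance-explained summaries
#' (fixed effects alone vs. fixed + random) are included.
#'
#' @param trials trimmed trial table with `sqrt_rt`.
#' @param formula fixed-effects formula; default
#'   `sqrt_rt ~ group * structure * modality`.
#' @param random use participant + trial random intercepts.
#' @return a `gp_fit` (family `gaussian-mixed`) with `r2_marginal` and
#'   `r2_conditional`; the underlying model object is in `$model`.
#' @export
fit_rt <- function(trials, formula = sqrt_rt ~ group * structure * modality,
                   random = TRUE) {
  if (!"sqrt_rt" %in% names(trials))
    stop("no sqrt_rt column: run transform_rt() first")
  if (!isTRUE(attr(trials, "rt_trimmed")))
    warning("trial table is not RT-trimmed; fitting anyway")
  tt <- droplevels(trials)
  if ("structure" %in% names(tt) && any(tt$structure == "filler"))
    tt <- tt[tt$structure != "filler", ]

  if (random) {
    mixed_formula <- update(formula,
                            . ~ . + (1 | participant_id) + (1 | trial_id))
    model <- lmerTest::lmer(mixed_formula, data = tt)
    sm <- summary(model)$coefficients
    cf <- .coef_table(sm[, "Estimate"], sm[, "Std. Error"], sm[, "df"])
    vc <- as.data.frame(lme4::VarCorr(model))
    var_r <- sum(vc$vcov[vc$grp != "Residual"])
    var_e <- vc$vcov[vc$grp == "Residual"]
    var_f <- var(as.vector(model.matrix(model) %*% lme4::fixef(model)))
    r2m <- var_f / (var_f + var_r + var_e)
    r2c <- (var_f + var_r) / (var_f + var_r + var_e)
  } else {
    model <- lm(formula, data = tt)
    sm <- summary(model)$coefficients
    cf <- .coef_table(sm[, 1], sm[, 2], rep(model$df.residual, nrow(sm)))
    r2m <- summary(model)$r.squared
    r2c <- r2m
  }
  .new_fit(cf, family = "gaussian-mixed", n = nrow(tt), model = model,
           converged = TRUE, formula = formula,
           r2_marginal = r2m, r2_conditional = r2c)
}
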