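#' Fit the censoring models for one arm
#'
#' Pooled logistic models for remaining uncensored by the intercurrent event
#' (non-compliance) at month t, fitted to that arm's clone-months: a
#' denominator model with time-varying covariates and a numerator model with
#' baseline/time terms only, for weight stabilization.  The original study
#' delegates the weight-model covariates to an unavailable appendix; the
#' defaults here condition on the variables the regimes themselves condition
#' on — current CD4, an RNA-suppression indicator, the prophylaxis state —
#' plus a cubic in month.
#'
#' If the arm contains no ICE-censored month, a degenerate fit with
#' probability identically one is returned, so downstream weights are exactly
#' one (no-censoring identity).
#'
#' @param clone_months clone-month table from [clone_and_follow()].
#' @param arm 1 or 2.
#' @param denominator_formula,numerator_formula right-hand-side formulas over
#'   columns of `clone_months` (`rna_suppressed` is derived as `rna < 400`).
#' @return Object of class `censor_fit` with elements `numerator`,
#'   `denominator` (each a glm or the string `"none"`), `arm`.
#' @export
fit_censoring_model <- function(clone_months, arm,
    denominator_formula = ~ cd4 + rna_suppressed + on_prophylaxis +
      month + I(month^2) + I(month^3),
    numerator_formula = ~ month + I(month^2) + I(month^3)) {
  stopifnot(arm %in% c(1L, 2L))
  dat <- clone_months[clone_months$clone_arm == arm, , drop = FALSE]
  if (nrow(dat) == 0L) stop_ccw("no clone-months in arm ", arm)
  dat$rna_suppressed <- dat$rna < 400
  dat$uncensored <- !dat$censored_ice
  if (all(dat$uncensored)) {
    return(structure(list(numerator = "none", denominator = "none",
                          arm = arm), class = "censor_fit"))
  }
  fit1 <- function(rhs) {
    f <- stats::update.formula(rhs, uncensored ~ .)
    fit <- suppressWarnings(glm(f, family = binomial(), data = dat,
                                control = list(epsilon = 1e-8,
                                               maxit = 100)))
    if (!fit$converged)
      stop_ccw("censoring model did not converge in arm ", arm,
               " (covariates: ", deparse(rhs[[2]]), ")")
    if (any(fitted(fit) < 1e-8))
      warning("censoring model in arm ", arm,
              " has fitted uncensored-probabilities near zero ",
              "(possible separation)", call. = FALSE)
    fit
  }
  structure(list(numerator = fit1(numerator_formula),
                 denominator = fit1(denominator_formula),
                 arm = arm), class = "censor_fit")
}

predict_uncensored <- function(model, dat) {
  if (identical(model, "none")) return(rep(1, nrow(dat)))
  as.numeric(predict(model, newdata = dat, type = "response"))
}

#' Compute stabilized inverse-probability-of-censoring weights
#'
#' For each clone the weight at month t is the cumulative product over months
#' 0..t of the ratio numerator/denominator of the fitted probabilities of
#' remaining uncensored by the intercurrent event.  Weights above the
#' truncation percentile are capped and flagged; denominator probabilities
#' below the positivity floor raise an error.
#'
#' @param fits list of two [fit_censoring_model()] results (arms 1 and 2).
#' @param clone_months clone-month table.
#' @param truncation_percentile cap quantile in (0, 1]; `1` disables
#'   truncation (default 0.99).
#' @param positivity_floor minimum tolerated denominator probability
#'   (default 1e-6).
#' @return `clone_months` with added columns `p_uncensored_numerator`,
#'   `p_uncensored_denominator`, `weight`, `truncated`.
#' @export
compute_stabilized_weights <- function(fits, clone_months,
                                       truncation_percentile = 0.99,
                                       positivity_floor = 1e-6) {
  stopifnot(length(fits) == 2L, inherits(fits[[1]], "censor_fit"),
            inherits(fits[[2]], "censor_fit"),
            truncation_percentile > 0, truncation_percentile <= 1)
  dat <- clone_months
  dat$rna_suppressed <- dat$rna < 400
  num <- den <- rep(NA_real_, nrow(dat))
  for (arm in 1:2) {
    idx <- dat$clone_arm == arm
    fit <- if (fits[[1]]$arm == arm) fits[[1]] else fits[[2]]
    num[idx] <- predict_uncensored(fit$numerator, dat[idx, , drop = FALSE])
    den[idx] <- predict_uncensored(fit$denominator, dat[idx, , drop = FALSE])
  }
  if (any(den < positivity_floor))
    stop_ccw(sprintf(
      "positivity violation: %d clone-months with denominator probability < %g",
      sum(den < positivity_floor), positivity_floor))
  res <- clone_months
  res$p_uncensored_numerator <- num
  res$p_uncensored_denominator <- den
  # cumulative product of the monthly ratios within clone, months ordered
  key <- paste(res$patient_id, res$clone_arm, sep = "\r")
  ord <- order(key, res$month)
  weight <- numeric(nrow(res))
  weight[ord] <- stats::ave((num / den)[ord], key[ord], FUN = cumprod)
  res$weight <- weight
  res$truncated <- FALSE
  if (truncation_percentile < 1) {
    cap <- as.numeric(quantile(res$weight, truncation_percentile,
                               names = FALSE))
    res$truncated <- res$weight > cap
    res$weight <- pmin(res$weight, cap)
  }
  res
}

#' One-call IPCW estimation
#'
#' Fits the per-arm censoring models and attaches stabilized weights; thin
#' wrapper around [fit_censoring_model()] and
#' [compute_stabilized_weights()].
#'
#' @inheritParams fit_censoring_model
#' @inheritParams compute_stabilized_weights
#' @return Weighted clone-month table.
#' @export
estimate_ipcw <- function(clone_months,
    denominator_formula = ~ cd4 + rna_suppressed + on_prophylaxis +
      month + I(month^2) + I(month^3),
    numerator_formula = ~ month + I(month^2) + I(month^3),
    truncation_percentile = 0.99, positivity_floor = 1e-6) {
  fits <- lapply(1:2, function(a)
    fit_censoring_model(clone_months, a,
                        denominator_formula = denominator_formula,
                        numerator_formula = numerator_formula))
  compute_stabilized_weights(fits, clone_months,
                             truncation_percentile = truncation_percentile,
                             positivity_floor = positivity_floor)
}
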