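#' Fit the weighted discrete-time pooled logistic hazard model
#'
#' Maximum-likelihood fit of the monthly event probability on the clone-month
#' (person-period) table, weighted by the stabilized IPC weights.  The
#' default model is the primary-analysis specification: an indicator for the
#' regime, a cubic baseline hazard in month, and a month-by-regime
#' interaction,
#' `logit h(t) = b0 + b1 t + b2 t^2 + b3 t^3 + theta arm2 + gamma t arm2`.
#'
#' ICE-censored clone-months (`censored_ice`) are excluded from the fit (they
#' carry no outcome information under the while-on-regime strategy; they
#' enter through the weights instead).  A missing `weight` column means unit
#' weights.
#'
#' @param clone_months weighted clone-month table ([estimate_ipcw()]); must
#'   contain `event`, `month`, `clone_arm` and the formula's covariates.
#'   `arm2` is derived as `clone_arm == 2`.
#' @param formula_spec model formula with `event` on the left (default the
#'   primary specification above).
#' @return Object of class `hazard_fit`: `coefficients`, `covariance`,
#'   `n_clone_months`, `converged`, `formula`, plus the underlying `glm`.
#' @export
fit_pooled_logistic <- function(clone_months,
    formula_spec = event ~ month + I(month^2) + I(month^3) + arm2 +
      month:arm2) {
  dat <- clone_months[!clone_months$censored_ice, , drop = FALSE]
  if (nrow(dat) == 0L) stop_ccw("no uncensored clone-months to fit")
  dat$arm2 <- as.integer(dat$clone_arm == 2L)
  if (!"weight" %in% names(dat)) dat$weight <- 1
  if (all(dat$weight == 0)) stop_ccw("all weights are zero")
  if (all(dat$event)) stop_ccw("degenerate fit: every clone-month is an event")
  if (!any(dat$event)) stop_ccw("degenerate fit: no events in the data")
  uses_arm <- "arm2" %in% all.vars(formula_spec)
  if (uses_arm && length(unique(dat$arm2)) < 2L)
    stop_ccw("single-arm input but the model formula includes the regime term")
  fit <- suppressWarnings(glm(formula_spec, family = binomial(), data = dat,
                              weights = weight,
                              control = list(epsilon = 1e-10, maxit = 100)))
  if (!fit$converged) stop_ccw("pooled logistic model did not converge")
  structure(list(coefficients = coef(fit), covariance = vcov(fit),
                 n_clone_months = nrow(dat), converged = fit$converged,
                 formula = formula_spec, glm = fit),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("<hazard_fit> %d clone-months, %d coefficients, %s\n",
              x$n_clone_months, length(x$coefficients),
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coefficients, 4))
  invisible(x)
}

theta_name <- function(fit) {
  nm <- names(fit$coefficients)
  hit <- nm[nm == "arm2"]
  if (!length(hit)) stop_ccw("model has no regime main effect (arm2)")
  hit
}

gamma_name <- function(fit) {
  nm <- names(fit$coefficients)
  nm[nm %in% c("month:arm2", "arm2:month")][1]
}

#' Summarise the regime hazard ratio from a fitted model
#'
#' The study's population-level summary is a single hazard ratio over the
#' whole follow-up period even though the model carries a month-by-regime
#' interaction; how the interaction is collapsed is a reporting choice:
#'
#' * `"main-effect"` (default): `exp(theta)`, the regime contrast at month 0
#'   (equal to the common HR whenever `gamma = 0`).
#' * `"time-averaged"`: `exp` of the person-time-weighted mean of
#'   `theta + gamma t` over months `0..horizon-1`.
#'
#' Confidence intervals and p-values are Wald on the log scale using the
#' model covariance (delta method for the time average); for resampling-based
#' intervals see [bootstrap_ci()].
#'
#' @param fit a [fit_pooled_logistic()] result.
#' @param method `"main-effect"` or `"time-averaged"`.
#' @param horizon months of follow-up averaged over (default 60).
#' @param person_time optional non-negative weights of length `horizon` for
#'   the time average (default uniform).
#' @param level confidence level (default 0.95).
#' @return Object of class `hr_estimate`: `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `log_hr`, `se_log_hr`, `method`.
#' @export
summarise_hr <- function(fit, method = c("main-effect", "time-averaged"),
                         horizon = 60L, person_time = NULL, level = 0.95) {
  stopifnot(inherits(fit, "hazard_fit"))
  if (!fit$converged) stop_ccw("cannot summarise a non-converged fit")
  method <- match.arg(method)
  th <- theta_name(fit)
  if (method == "main-effect") {
    est <- unname(fit$coefficients[th])
    se <- sqrt(fit$covariance[th, th])
  } else {
    ga <- gamma_name(fit)
    t <- seq_len(horizon) - 1
    w <- person_time %||% rep(1, horizon)
    stopifnot(length(w) == horizon, all(w >= 0), sum(w) > 0)
    tbar <- sum(w * t) / sum(w)
    if (is.na(ga)) {
      est <- unname(fit$coefficients[th])
      se <- sqrt(fit$covariance[th, th])
    } else {
      est <- unname(fit$coefficients[th] + tbar * fit$coefficients[ga])
      se <- sqrt(fit$covariance[th, th] + tbar^2 * fit$covariance[ga, ga] +
                 2 * tbar * fit$covariance[th, ga])
    }
  }
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(hr = exp(est), ci_low = exp(est - z * se),
                 ci_high = exp(est + z * se),
                 p_value = 2 * pnorm(-abs(est / se)),
                 log_hr = est, se_log_hr = se, method = method,
                 bootstrap_reps = 0L),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("HR %.3f [%.3f, %.3f], p %s  (%s%s)\n", x$hr, x$ci_low,
              x$ci_high,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value),
              x$method,
              if (x$bootstrap_reps > 0)
                sprintf(", %d bootstrap reps", x$bootstrap_reps) else ""))
  invisible(x)
}

#' Per-arm discrete-time survival curves
#'
#' `S(t) = prod_{s < t} (1 - h(s))` at the model's reference covariates,
#' with `h(s)` the fitted monthly event probability in each arm.
#'
#' @param fit a converged [fit_pooled_logistic()] whose formula uses only
#'   `month` and `arm2` terms.
#' @param horizon months (default 60); the curve is returned at t = 0..horizon.
#' @return Data frame with columns `clone_arm`, `month`, `hazard` (`NA` at
#'   `t = horizon`), `surv`.
#' @export
survival_curves <- function(fit, horizon = 60L) {
  stopifnot(inherits(fit, "hazard_fit"))
  if (!fit$converged) stop_ccw("cannot predict from a non-converged fit")
  vars <- setdiff(all.vars(fit$formula), "event")
  if (!all(vars %in% c("month", "arm2")))
    stop_ccw("survival_curves() supports formulas in month and arm2 only")
  out <- lapply(1:2, function(arm) {
    nd <- data.frame(month = seq_len(horizon) - 1,
                     arm2 = as.integer(arm == 2L))
    h <- as.numeric(predict(fit$glm, newdata = nd, type = "response"))
    data.frame(clone_arm = arm, month = 0:horizon,
               hazard = c(h, NA_real_),
               surv = cumprod(c(1, 1 - h)))
  })
  do.call(rbind, out)
}

#' Patient-level bootstrap confidence interval for the hazard ratio
#'
#' Resamples *patients* with replacement (both clones of a resampled patient
#' enter together — the clones of one person are not independent, so
#' clone-month resampling would understate the variance) and re-runs the
#' pipeline on each replicate.  Eligibility screening and cloning are
#' deterministic per patient, so the per-patient clone blocks are computed
#' once and resampled; the stages that pool information across patients —
#' censoring-weight estimation and the outcome fit — are re-estimated on
#' every replicate.  Returns the percentile CI of the HR and a two-sided
#' normal-approximation p-value on the log scale using the bootstrap
#' standard error.
#'
#' @param visits cohort table.
#' @param opts an [analysis_options()] bundle.
#' @param n_reps number of bootstrap replicates (>= 2).
#' @param seed integer seed; fixed seed gives identical CIs.
#' @param level confidence level (default 0.95).
#' @return An `hr_estimate` (point estimate from the original data).
#' @export
bootstrap_ci <- function(visits, opts = analysis_options(), n_reps = 200L,
                         seed = 1L, level = 0.95) {
  stopifnot(n_reps >= 2L)
  ids <- unique(visits$patient_id)
  if (length(ids) < 2L)
    stop_ccw("bootstrap requires at least 2 patients, got ", length(ids))
  full <- emulate_and_fit(visits, opts)
  est0 <- summarise_hr(full$fit, method = opts$hr_method,
                       horizon = opts$horizon)
  cm0 <- full$clone_months
  block <- split(seq_len(nrow(cm0)), cm0$patient_id)
  cids <- names(block)
  set.seed(seed)
  log_hrs <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    take <- sample(cids, length(cids), replace = TRUE)
    rows <- block[take]
    boot <- cm0[unlist(rows, use.names = FALSE), , drop = FALSE]
    boot$patient_id <- rep.int(sprintf("b%06d", seq_along(take)),
                               lengths(rows))
    log_hrs[r] <- tryCatch({
      bw <- estimate_ipcw(boot,
                          denominator_formula = opts$denominator_formula,
                          numerator_formula = opts$numerator_formula,
                          truncation_percentile = opts$truncation_percentile)
      fit <- fit_pooled_logistic(bw, formula_spec = opts$outcome_formula)
      summarise_hr(fit, method = opts$hr_method,
                   horizon = opts$horizon)$log_hr
    }, error = function(e) NA_real_)
  }
  fail <- mean(is.na(log_hrs))
  if (fail > 0.2)
    stop_ccw(sprintf("bootstrap aborted: %.0f%% of replicates failed to fit",
                     100 * fail))
  if (fail > 0)
    message(sprintf("bootstrap: %d/%d replicates failed and were skipped",
                    sum(is.na(log_hrs)), n_reps))
  log_hrs <- log_hrs[!is.na(log_hrs)]
  alpha <- 1 - level
  ci <- quantile(log_hrs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  se <- stats::sd(log_hrs)
  structure(list(hr = est0$hr, ci_low = exp(ci[1]), ci_high = exp(ci[2]),
                 p_value = 2 * pnorm(-abs(est0$log_hr / se)),
                 log_hr = est0$log_hr, se_log_hr = se,
                 method = est0$method, bootstrap_reps = length(log_hrs)),
            class = "hr_estimate")
}
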