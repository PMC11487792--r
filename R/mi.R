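#' Sensitivity-analysis scenarios for loss to follow-up
#'
#' Which hazard do patients adopt after dropping out?
#'
#' * `"car"` — censoring at random: post-LTFU months are imputed from the
#'   own-arm on-regime hazard (the primary-analysis model refitted to the
#'   observed clone-months).  A congeniality cross-check: it should reproduce
#'   the primary analysis up to Monte-Carlo noise.
#' * `"j2op"` — "jump to off prophylaxis": the imputation model is fitted to
#'   the clone-months of patients off prophylaxis (pooled over arms, regime
#'   terms dropped), and every LTFU clone in either arm adopts that hazard.
#' * `"j2op-arm2"` — the asymmetric post-hoc variant: only clones assigned to
#'   regime 2 jump to the off-prophylaxis hazard; regime-1 clones stay
#'   censored at LTFU exactly as in the primary analysis.
#'
#' @param name scenario token.
#' @return Object of class `mi_scenario` with fields `name`, `arms_imputed`
#'   (`1:2` or `2`), `reference` (`"own-arm"` or `"off-prophylaxis"`).
#' @export
mi_scenario <- function(name = c("car", "j2op", "j2op-arm2")) {
  name <- match.arg(name)
  structure(list(name = name,
                 arms_imputed = if (name == "j2op-arm2") 2L else 1:2,
                 reference = if (name == "car") "own-arm"
                             else "off-prophylaxis"),
            class = "mi_scenario")
}

#' Fit the imputation model to a scenario's reference group
#'
#' The imputation model is the pooled logistic hazard model of the primary
#' analysis, refitted to the scenario's reference clone-months: for CAR the
#' observed on-regime months of both arms (regime terms retained); for
#' jump-to-off-prophylaxis the months in which patients were off prophylaxis
#' (pooled across arms, regime terms dropped — the reference hazard is
#' off-prophylaxis behaviour itself).
#'
#' @param clone_months clone-month table (weighted or not; the imputation
#'   model itself is unweighted, being a model of the reference group's
#'   observed event process).
#' @param scenario an [mi_scenario()].
#' @param formula_spec model formula; defaults to the primary specification
#'   for CAR and to its time-only reduction for the jump scenarios.
#' @return A `hazard_fit` for the reference group.
#' @export
fit_imputation_model <- function(clone_months, scenario,
                                 formula_spec = NULL) {
  stopifnot(inherits(scenario, "mi_scenario"))
  obs <- clone_months[!clone_months$imputed & !clone_months$censored_ice, ,
                      drop = FALSE]
  if (scenario$reference == "off-prophylaxis") {
    ref <- obs[!obs$on_prophylaxis, , drop = FALSE]
    formula_spec <- formula_spec %||%
      (event ~ month + I(month^2) + I(month^3))
  } else {
    ref <- obs
    formula_spec <- formula_spec %||%
      (event ~ month + I(month^2) + I(month^3) + arm2 + month:arm2)
  }
  if (nrow(ref) == 0L)
    stop_ccw("empty reference group for scenario '", scenario$name,
             "' (no one ever stopped prophylaxis?)")
  if (!any(ref$event))
    stop_ccw("no events in the reference group for scenario '",
             scenario$name, "'")
  ref$weight <- 1
  fit_pooled_logistic(ref, formula_spec = formula_spec)
}

#' Draw imputation-model parameters (proper MI)
#'
#' One draw from the multivariate-normal approximation to the sampling
#' distribution of the reference model's coefficients, so each imputation
#' propagates parameter uncertainty (approximate Bayesian proper MI).
#' Deterministic given the RNG state.
#'
#' @param fit a converged `hazard_fit` with positive-semidefinite covariance.
#' @return Named numeric coefficient vector.
#' @export
draw_parameters <- function(fit) {
  stopifnot(inherits(fit, "hazard_fit"))
  if (!fit$converged) stop_ccw("cannot draw from a non-converged fit")
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop_ccw("coefficient covariance is not positive semi-definite")
  drop(MASS::mvrnorm(1, mu = fit$coefficients, Sigma = fit$covariance,
                     tol = 1e-6))
}

# rows of clones whose follow-up terminates in LTFU, restricted to arms in
# scope; returns per-clone censoring month
ltfu_index <- function(clone_months, arms) {
  lt <- clone_months[clone_months$censored_ltfu &
                     clone_months$clone_arm %in% arms, , drop = FALSE]
  lt[, c("patient_id", "clone_arm", "month")]
}

#' Multiply impute post-LTFU event histories
#'
#' For each LTFU clone with censoring month `c`, draws monthly Bernoulli
#' event indicators for months `c+1 .. horizon-1` with probability
#' `expit(x(t)' beta)` under the drawn reference-model coefficients;
#' follow-up completes at the first imputed event or the administrative
#' horizon.  Imputed records are flagged `imputed = TRUE`, receive unit
#' weight in the outcome refit (IPC weights are defined only over observed
#' follow-up), carry last-observed CD4/RNA forward, and have unknown
#' (`NA`) prophylaxis state.  The LTFU flag of month `c` is cleared in the
#' completed history.  A clone censored in the final month has nothing to
#' impute and is completed as an administrative end.
#'
#' @param clone_months clone-month table.
#' @param draw coefficient vector from [draw_parameters()].
#' @param formula_spec the imputation-model formula the draw belongs to.
#' @param arms arms whose LTFU clones are imputed (`1:2` or `2`).
#' @param horizon administrative horizon (default 60).
#' @return The completed clone-month table (observed rows plus imputed
#'   extensions, ordered by patient, arm, month).
#' @export
impute_event_times <- function(clone_months, draw, formula_spec,
                               arms = 1:2, horizon = 60L) {
  idx <- ltfu_index(clone_months, arms)
  out <- clone_months
  if (nrow(idx) == 0L) return(out)
  rhs <- stats::delete.response(stats::terms(formula_spec))
  key_all <- paste(out$patient_id, out$clone_arm)
  key_lt <- paste(idx$patient_id, idx$clone_arm)
  pieces <- vector("list", nrow(idx))
  for (j in seq_len(nrow(idx))) {
    cmonth <- idx$month[j]
    sel <- key_all == key_lt[j] & out$month == cmonth
    out$censored_ltfu[sel] <- FALSE
    if (cmonth >= horizon - 1L) {         # nothing left to impute
      out$admin_end[sel] <- TRUE
      next
    }
    t <- seq.int(cmonth + 1L, horizon - 1L)
    nd <- data.frame(month = t, arm2 = as.integer(idx$clone_arm[j] == 2L))
    X <- model.matrix(rhs, nd)
    p <- expit(drop(X %*% draw[colnames(X)]))
    fire <- which(rbinom(length(t), 1L, p) == 1L)[1]
    last <- if (is.na(fire)) length(t) else fire
    tt <- t[seq_len(last)]
    ev <- rep(FALSE, last); ev[last] <- !is.na(fire)
    base <- out[sel, , drop = FALSE]
    pieces[[j]] <- data.frame(
      patient_id = idx$patient_id[j], clone_arm = idx$clone_arm[j],
      month = tt, cd4 = base$cd4, rna = base$rna,
      on_prophylaxis = NA, event = ev,
      event_pcp = FALSE, event_death = ev,   # composite: type label only
      censored_ice = FALSE, censored_ltfu = FALSE,
      admin_end = c(rep(FALSE, last - 1L), is.na(fire)),
      imputed = TRUE, stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces)) {
    ext <- do.call(rbind, pieces)
    for (col in setdiff(names(out), names(ext))) ext[[col]] <- NA
    ext$weight <- 1
    out <- rbind(out, ext[, names(out)])
  }
  out <- out[order(out$patient_id, out$clone_arm, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a reference-based multiple-imputation sensitivity analysis
#'
#' For each of `m` imputations: draw reference-model parameters, impute the
#' scenario's LTFU clones to the horizon, refit the weighted outcome model on
#' the completed data (observed months keep their IPC weights, imputed months
#' get weight 1), and record the log-HR estimate and its variance; then pool
#' with Rubin's rules and Barnard-Rubin degrees of freedom.  With zero LTFU
#' clones in scope, imputation is a no-op and the result equals the primary
#' analysis exactly.
#'
#' @param clone_months weighted clone-month table from [estimate_ipcw()].
#' @param scenario an [mi_scenario()] (or its name token).
#' @param m number of imputations (default 25).
#' @param seed integer seed; fixed seed gives identical results.
#' @param outcome_formula outcome-model formula (primary specification by
#'   default).
#' @param imputation_formula optional override of the imputation-model
#'   formula.
#' @param hr_method which log-HR contrast is pooled: the month-0 regime
#'   main effect (`"main-effect"`, default) or the person-time-averaged
#'   whole-period contrast (`"time-averaged"`; matches the estimand when the
#'   month-by-regime interaction is non-zero, e.g. after imputation changes
#'   the late-month person-time composition).
#' @param horizon administrative horizon (default 60).
#' @param level confidence level (default 0.95).
#' @return Object of class `mi_result`; see [rubin_pool()] for the pooled
#'   components.
#' @export
run_mi <- function(clone_months, scenario = mi_scenario("j2op"), m = 25L,
                   seed = 1L,
                   outcome_formula = event ~ month + I(month^2) +
                     I(month^3) + arm2 + month:arm2,
                   imputation_formula = NULL,
                   hr_method = c("main-effect", "time-averaged"),
                   horizon = 60L, level = 0.95) {
  if (is.character(scenario)) scenario <- mi_scenario(scenario)
  hr_method <- match.arg(hr_method)
  stopifnot(inherits(scenario, "mi_scenario"), m >= 2L)
  primary <- fit_pooled_logistic(clone_months, formula_spec = outcome_formula)
  c0 <- mi_contrast(primary, hr_method, horizon)
  q0 <- c0$q
  u0 <- c0$u
  n_ltfu <- nrow(ltfu_index(clone_months, scenario$arms_imputed))
  if (n_ltfu == 0L) {
    pooled <- rubin_pool(rep(q0, m), rep(u0, m),
                         df_com = primary$n_clone_months -
                           length(primary$coefficients), level = level)
    return(structure(c(list(scenario = scenario$name, m = m,
                            n_ltfu_clones = 0L, hr_method = hr_method,
                            per_imputation = data.frame(
                              estimate = rep(q0, m),
                              variance = rep(u0, m))),
                       pooled), class = "mi_result"))
  }
  imp_fit <- fit_imputation_model(clone_months, scenario,
                                  formula_spec = imputation_formula)
  set.seed(seed)
  qs <- us <- rep(NA_real_, m)
  df_com <- NA_real_
  for (j in seq_len(m)) {
    res <- tryCatch({
      draw <- draw_parameters(imp_fit)
      comp <- impute_event_times(clone_months, draw, imp_fit$formula,
                                 arms = scenario$arms_imputed,
                                 horizon = horizon)
      fit <- fit_pooled_logistic(comp, formula_spec = outcome_formula)
      df_com <- fit$n_clone_months - length(fit$coefficients)
      cj <- mi_contrast(fit, hr_method, horizon)
      c(cj$q, cj$u)
    }, error = function(e) c(NA_real_, NA_real_))
    qs[j] <- res[1]; us[j] <- res[2]
  }
  fail <- mean(is.na(qs))
  if (fail > 0.2)
    stop_ccw(sprintf("MI aborted: %.0f%% of imputations failed to fit",
                     100 * fail))
  if (fail > 0)
    message(sprintf("MI: %d/%d imputations failed and were skipped",
                    sum(is.na(qs)), m))
  keep <- !is.na(qs)
  pooled <- rubin_pool(qs[keep], us[keep], df_com = df_com, level = level)
  structure(c(list(scenario = scenario$name, m = sum(keep),
                   n_ltfu_clones = n_ltfu, hr_method = hr_method,
                   per_imputation = data.frame(estimate = qs[keep],
                                               variance = us[keep])),
              pooled), class = "mi_result")
}

# log-HR contrast and its variance on one fitted model; exact covariance
# algebra (no sqrt round-trip) so no-missing identities hold bit-for-bit
mi_contrast <- function(fit, method, horizon) {
  th <- theta_name(fit)
  if (method == "main-effect")
    return(list(q = unname(fit$coefficients[th]),
                u = fit$covariance[th, th]))
  ga <- gamma_name(fit)
  tbar <- mean(seq_len(horizon) - 1)
  if (is.na(ga))
    return(list(q = unname(fit$coefficients[th]),
                u = fit$covariance[th, th]))
  list(q = unname(fit$coefficients[th] + tbar * fit$coefficients[ga]),
       u = fit$covariance[th, th] + tbar^2 * fit$covariance[ga, ga] +
         2 * tbar * fit$covariance[th, ga])
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf(
    "<mi_result '%s'> m = %d, %d LTFU clones imputed\nHR %.3f [%.3f, %.3f], p %s (df %.1f)\n",
    x$scenario, x$m, x$n_ltfu_clones, x$hr, x$ci_low, x$ci_high,
    if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value),
    x$df))
  invisible(x)
}

#' Pool multiple-imputation estimates by Rubin's rules
#'
#' Pooled estimate `Qbar = mean(Q_j)`; within-imputation variance
#' `Wbar = mean(U_j)`; between-imputation variance `B = var(Q_j)`; total
#' variance `T = Wbar + (1 + 1/m) B`; Barnard-Rubin small-sample degrees of
#' freedom; t-based confidence interval and two-sided p-value on the log
#' scale, plus the exponentiated summaries.
#'
#' @param estimates per-imputation log-HR estimates (length m >= 2).
#' @param variances per-imputation variances (same length).
#' @param df_com complete-data degrees of freedom (default `Inf`, which
#'   reduces Barnard-Rubin to the classical Rubin df).
#' @param level confidence level.
#' @return List: `pooled_estimate`, `within_variance`, `between_variance`,
#'   `total_variance`, `df`, `hr`, `ci_low`, `ci_high`, `p_value`.
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf, level = 0.95) {
  m <- length(estimates)
  if (m < 2L || length(variances) != m)
    stop_ccw("rubin_pool() needs equal-length estimate/variance vectors, m >= 2")
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- var(estimates)
  tt <- wbar + (1 + 1 / m) * b
  lambda <- if (tt > 0) (1 + 1 / m) * b / tt else 0
  if (lambda < .Machine$double.eps) {
    df <- if (is.finite(df_com)) df_com else Inf
  } else {
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  }
  se <- sqrt(tt)
  qcrit <- if (is.finite(df)) qt(1 - (1 - level) / 2, df)
           else qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) as.numeric(qbar == 0)
       else if (is.finite(df)) 2 * pt(-abs(qbar / se), df)
       else 2 * pnorm(-abs(qbar / se))
  list(pooled_estimate = qbar, within_variance = wbar, between_variance = b,
       total_variance = tt, df = df,
       hr = exp(qbar), ci_low = exp(qbar - qcrit * se),
       ci_high = exp(qbar + qcrit * se), p_value = p)
}
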