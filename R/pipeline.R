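#' Bundle the analysis options of one emulated-trial run
#'
#' Collects every tunable of the simulate-emulate-weight-fit-impute pipeline
#' in one object so the whole analysis is reproducible from a single
#' configuration.
#'
#' @param criteria an [eligibility_criteria()].
#' @param regimes list of two [regime_spec()]s.
#' @param grace compliance grace period in months (default 1).
#' @param horizon administrative horizon in months (default 60).
#' @param denominator_formula,numerator_formula censoring-model covariates
#'   (see [fit_censoring_model()]).
#' @param truncation_percentile weight-truncation quantile (default 0.99).
#' @param outcome_formula outcome-model formula (primary specification).
#' @param hr_method `"main-effect"` or `"time-averaged"`
#'   (see [summarise_hr()]).
#' @param randomized treat the cohort as a randomized behaviour-assigned
#'   trial: keep only each patient's own-strategy clone (see
#'   [as_randomized_trial()]); requires a simulated cohort with
#'   `behaviour_regime`.
#' @param scenarios character vector of MI scenario tokens to run after the
#'   primary analysis (subset of `c("car", "j2op", "j2op-arm2")`).
#' @param m number of imputations per scenario (default 25).
#' @param bootstrap_reps patient-level bootstrap replicates for the primary
#'   CI; 0 (default) uses the Wald model-based interval instead.
#' @return Object of class `analysis_options`.
#' @export
analysis_options <- function(criteria = eligibility_criteria(),
                             regimes = list(regime_cd4(), regime_rna()),
                             grace = 1L, horizon = 60L,
                             denominator_formula = ~ cd4 + rna_suppressed +
                               on_prophylaxis + month + I(month^2) +
                               I(month^3),
                             numerator_formula = ~ month + I(month^2) +
                               I(month^3),
                             truncation_percentile = 0.99,
                             outcome_formula = event ~ month + I(month^2) +
                               I(month^3) + arm2 + month:arm2,
                             hr_method = c("main-effect", "time-averaged"),
                             randomized = FALSE,
                             scenarios = c("car", "j2op", "j2op-arm2"),
                             m = 25L, bootstrap_reps = 0L) {
  hr_method <- match.arg(hr_method)
  check_flag(randomized, "randomized")
  stopifnot(inherits(criteria, "eligibility_criteria"),
            length(regimes) == 2L,
            all(scenarios %in% c("car", "j2op", "j2op-arm2")) ||
              length(scenarios) == 0L)
  structure(list(criteria = criteria, regimes = regimes,
                 grace = as.integer(grace), horizon = as.integer(horizon),
                 denominator_formula = denominator_formula,
                 numerator_formula = numerator_formula,
                 truncation_percentile = truncation_percentile,
                 outcome_formula = outcome_formula, hr_method = hr_method,
                 randomized = randomized, scenarios = scenarios,
                 m = as.integer(m),
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "analysis_options")
}

#' Screen, clone, weight and fit in one call
#'
#' The primary-analysis path: eligibility screening, cloning and censoring,
#' stabilized IPCW estimation, and the weighted pooled logistic outcome fit.
#'
#' @param visits cohort table.
#' @param opts an [analysis_options()].
#' @return List: `time0`, `clone_months` (weighted), `fit` (a `hazard_fit`).
#' @export
emulate_and_fit <- function(visits, opts = analysis_options()) {
  time0 <- screen_eligibility(visits, opts$criteria)
  if (length(time0) == 0L) stop_ccw("no eligible patients in the cohort")
  cm <- clone_and_follow(visits, time0, regimes = opts$regimes,
                         grace = opts$grace, horizon = opts$horizon)
  if (opts$randomized) cm <- as_randomized_trial(cm, visits)
  cm <- estimate_ipcw(cm,
                      denominator_formula = opts$denominator_formula,
                      numerator_formula = opts$numerator_formula,
                      truncation_percentile = opts$truncation_percentile)
  fit <- fit_pooled_logistic(cm, formula_spec = opts$outcome_formula)
  list(time0 = time0, clone_months = cm, fit = fit)
}

#' Two-proportion chi-square test
#'
#' The descriptive-table test: a chi-square test without continuity
#' correction comparing one proportion between the two regimes.
#'
#' @param x1,x2 event counts per arm.
#' @param n1,n2 arm sizes.
#' @return Two-sided p-value.
#' @export
two_prop_chisq <- function(x1, n1, x2, n2) {
  if (x1 == x2 && n1 == n2) return(1)
  suppressWarnings(
    prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
}

#' Descriptive table of the emulated trial
#'
#' Per-arm patient counts at baseline and counts/percentages of PcP
#' diagnoses, deaths, the composite event, and loss to follow-up over
#' follow-up, with two-proportion chi-square p-values comparing the regimes.
#' Percentages are count/N-at-baseline x 100 (the package's stated
#' denominator), printed to one decimal, as are the p-values.
#'
#' @param clone_months clone-month table with terminal states marked.
#' @return Data frame with columns `row`, `count_1`, `pct_1`, `count_2`,
#'   `pct_2`, `p_value`.
#' @export
descriptive_table <- function(clone_months) {
  obs <- clone_months[!clone_months$imputed, , drop = FALSE]
  n <- vapply(1:2, function(a)
    length(unique(obs$patient_id[obs$clone_arm == a])), integer(1))
  cnt <- function(col) vapply(1:2, function(a)
    sum(obs[[col]][obs$clone_arm == a]), numeric(1))
  rows <- list(`Event: PcP diagnosis` = cnt("event_pcp"),
               `Event: Died` = cnt("event_death"),
               `Event: PcP diagnosis/death` = cnt("event"),
               `Lost to follow-up (LTFU)` = cnt("censored_ltfu"))
  out <- data.frame(row = c("Total patients", names(rows)),
                    count_1 = c(n[1], vapply(rows, `[`, numeric(1), 1)),
                    pct_1 = NA_real_,
                    count_2 = c(n[2], vapply(rows, `[`, numeric(1), 2)),
                    pct_2 = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in 2:nrow(out)) {
    out$pct_1[r] <- round(100 * out$count_1[r] / n[1], 1)
    out$pct_2[r] <- round(100 * out$count_2[r] / n[2], 1)
    out$p_value[r] <- round(two_prop_chisq(out$count_1[r], n[1],
                                           out$count_2[r], n[2]), 1)
  }
  rownames(out) <- NULL
  out
}

format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}

#' Run the full emulated-trial pipeline
#'
#' Orchestrates simulate (or load) -> screen -> clone-censor -> weight ->
#' fit -> impute -> pool, returning (and optionally writing) a results table
#' with one row per analysis — primary IPW plus each configured MI scenario —
#' alongside the descriptive table, mirroring the standard report layout of
#' this design.
#'
#' @param cohort a [cohort_config()] (the cohort is simulated), a cohort data
#'   frame, or a path to a cohort CSV.
#' @param opts an [analysis_options()].
#' @param seed seed for bootstrap/imputation randomness (default 1).
#' @param out_dir optional output directory: writes `cohort.csv` (when
#'   simulated), `clone_months.csv`, `descriptive.csv`, `results.csv`,
#'   `survival.csv` and `run_log.txt` (configuration echo, stage markers,
#'   weight summary).
#' @return Object of class `ccw_run`: `descriptive`, `results` (one row per
#'   analysis with HR, CI, p), `fit`, `mi` (list of `mi_result`),
#'   `clone_months`, `log` (character vector).
#' @export
run_pipeline <- function(cohort, opts = analysis_options(), seed = 1L,
                         out_dir = NULL) {
  log <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    log <<- c(log, line)
    message(line)
  }
  simulated <- inherits(cohort, "cohort_config")
  if (simulated) {
    say("stage simulate: n_patients=%d seed=%d", cohort$n_patients,
        cohort$seed)
    config <- cohort
    cohort <- simulate_cohort(config)
  } else if (is.character(cohort)) {
    say("stage load: %s", cohort)
    cohort <- read_cohort(cohort)
  }
  say("stage emulate: %d patients, grace=%d horizon=%d",
      length(unique(cohort$patient_id)), opts$grace, opts$horizon)
  run <- emulate_and_fit(cohort, opts)
  cm <- run$clone_months
  say("stage weight: mean=%.4f max=%.4f truncated=%d", mean(cm$weight),
      max(cm$weight), sum(cm$truncated))
  primary <- if (opts$bootstrap_reps >= 2L) {
    say("stage fit: primary + %d bootstrap reps", opts$bootstrap_reps)
    bootstrap_ci(cohort, opts, n_reps = opts$bootstrap_reps, seed = seed)
  } else {
    say("stage fit: primary (Wald interval)")
    summarise_hr(run$fit, method = opts$hr_method, horizon = opts$horizon)
  }
  results <- data.frame(
    analysis = "Primary analysis: HR under CAR (using IPW)",
    hr = primary$hr, ci_low = primary$ci_low, ci_high = primary$ci_high,
    p_value = primary$p_value, stringsAsFactors = FALSE)
  labels <- c(car = "Supplementary analysis: HR under CAR (IPW and MI for LTFU)",
              j2op = "Sensitivity analysis 1: HR under 'jump to off prophylaxis'",
              `j2op-arm2` =
                "Sensitivity analysis 2: 'jump to off prophylaxis', regime 2 only")
  mi <- list()
  for (sc in opts$scenarios) {
    say("stage impute: scenario=%s m=%d", sc, opts$m)
    res <- run_mi(cm, mi_scenario(sc), m = opts$m, seed = seed,
                  outcome_formula = opts$outcome_formula,
                  horizon = opts$horizon)
    mi[[sc]] <- res
    results <- rbind(results, data.frame(
      analysis = labels[[sc]], hr = res$hr, ci_low = res$ci_low,
      ci_high = res$ci_high, p_value = res$p_value,
      stringsAsFactors = FALSE))
  }
  desc <- descriptive_table(cm)
  say("stage report: %d analysis rows", nrow(results))
  out <- structure(list(descriptive = desc, results = results,
                        fit = run$fit, mi = mi, clone_months = cm,
                        primary = primary, log = log),
                   class = "ccw_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (simulated) write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write.csv(cm, file.path(out_dir, "clone_months.csv"), row.names = FALSE)
    write.csv(desc, file.path(out_dir, "descriptive.csv"),
              row.names = FALSE)
    res_out <- results
    res_out$p_value <- format_p(res_out$p_value)
    write.csv(res_out, file.path(out_dir, "results.csv"), row.names = FALSE)
    write.csv(survival_curves(run$fit, horizon = opts$horizon),
              file.path(out_dir, "survival.csv"), row.names = FALSE)
    writeLines(c(sprintf("ccwmi %s seed=%d",
                         as.character(packageVersion("ccwmi")), seed),
                 log), file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.ccw_run <- function(x, ...) {
  cat("Descriptive table\n")
  print(x$descriptive, row.names = FALSE)
  cat("\nAnalysis rows (HR [95% CI], p)\n")
  res <- x$results
  res$hr <- sprintf("%.2f", res$hr)
  res$ci <- sprintf("[%.2f, %.2f]", x$results$ci_low, x$results$ci_high)
  res$p <- format_p(x$results$p_value)
  print(res[, c("analysis", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}
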