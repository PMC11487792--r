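#' Configuration of the synthetic cohort generator
#'
#' Defines the stochastic world the simulator draws from: one record per
#' patient per month from cohort entry (start of cART) until the composite
#' PcP-or-death event, loss to follow-up (LTFU), or the administrative end of
#' study.  All hazards are monthly Bernoulli probabilities on the logit
#' scale, matching the discrete-time analysis downstream.
#'
#' The regime effect `log_hr_regime` is attached to the patient's behavioural
#' strategy (an indicator that the patient follows the viral-suppression
#' stopping strategy), so `exp(log_hr_regime)` is the known marginal truth a
#' randomized no-censoring analysis must recover; see [true_marginal_hr()].
#'
#' @param n_patients number of patients (>= 0).
#' @param max_months administrative end of follow-up in months (default 60,
#'   a 5-year study on a monthly grid).
#' @param baseline_cd4_meanlog,baseline_cd4_sdlog lognormal parameters of CD4
#'   at entry (defaults place ~90% of mass below 200 cells/uL, the
#'   prophylaxis-recommendation threshold).
#' @param cd4_recovery_rate mean monthly CD4 increase on cART (cells/uL;
#'   default 10, about +120/year in the first years of therapy).
#' @param cd4_noise_sdlog lognormal measurement/biological noise around the
#'   piecewise-linear CD4 mean (default 0.15).
#' @param rna_suppression_probability per-month probability of crossing below
#'   400 copies/ml; once suppressed, RNA stays suppressed (default 0.25,
#'   median time to suppression about 3 months).
#' @param log_hazard_intercept baseline monthly log-odds of the composite
#'   PcP/death event (default `qlogis(0.0015)`, about 8.6% cumulative
#'   incidence over 60 months).
#' @param log_hr_off_prophylaxis log odds ratio on the event for being off
#'   prophylaxis in the current month (default 0.4).
#' @param log_hr_regime true log hazard ratio of the suppression-guided
#'   strategy versus the CD4-guided strategy (default `log(0.78)`).
#' @param event_pcp_fraction probability that a composite event is a PcP
#'   diagnosis rather than a death (default 0.25).
#' @param ltfu_monthly_probability per-month LTFU probability (default 8e-4,
#'   about 4.7% over 60 months).
#' @param ltfu_informative_log_or extra LTFU log-odds in months off
#'   prophylaxis; 0 (default) gives censoring at random by construction.
#' @param behaviour prophylaxis-taking behaviour of the simulated patients:
#'   `"mixture"` (each patient follows regime 1 or regime 2, assigned with
#'   probability `p_regime2`), `"regime1"`, `"regime2"`, or `"random_stop"`
#'   (stop for good in a geometric random month, regardless of labs).
#' @param p_regime2 mixture weight of the suppression-guided strategy
#'   (default 0.5).
#' @param adherence_probability per-month probability that a patient
#'   conforms to their strategy's currently required prophylaxis state;
#'   otherwise they carry last month's state forward (behavioural lag).
#'   1 means exact rule-following; default 0.9, so compliance — and hence
#'   the intercurrent event — is stochastic given the recorded covariates,
#'   as the censoring-weight models assume.
#' @param random_stop_probability monthly stopping probability under
#'   `behaviour = "random_stop"` (default 0.05).
#' @param seed master seed; per-patient substreams are derived from it so
#'   changing `n_patients` does not reshuffle earlier patients.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()], [true_marginal_hr()]
#' @export
cohort_config <- function(n_patients,
                          max_months = 60L,
                          baseline_cd4_meanlog = log(100),
                          baseline_cd4_sdlog = 0.5,
                          cd4_recovery_rate = 10,
                          cd4_noise_sdlog = 0.15,
                          rna_suppression_probability = 0.25,
                          log_hazard_intercept = stats::qlogis(0.0015),
                          log_hr_off_prophylaxis = 0.4,
                          log_hr_regime = log(0.78),
                          event_pcp_fraction = 0.25,
                          ltfu_monthly_probability = 8e-4,
                          ltfu_informative_log_or = 0,
                          behaviour = c("mixture", "regime1", "regime2",
                                        "random_stop"),
                          p_regime2 = 0.5,
                          adherence_probability = 0.9,
                          random_stop_probability = 0.05,
                          seed = 1L) {
  behaviour <- match.arg(behaviour)
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 0 || n_patients != floor(n_patients))
    stop_ccw("`n_patients` must be a non-negative integer")
  if (!is.numeric(max_months) || max_months < 1)
    stop_ccw("`max_months` must be >= 1")
  check_prob(rna_suppression_probability, "rna_suppression_probability")
  check_prob(event_pcp_fraction, "event_pcp_fraction")
  check_prob(ltfu_monthly_probability, "ltfu_monthly_probability")
  check_prob(p_regime2, "p_regime2")
  check_prob(adherence_probability, "adherence_probability")
  check_prob(random_stop_probability, "random_stop_probability")
  stopifnot(is.numeric(log_hazard_intercept),
            is.numeric(log_hr_off_prophylaxis),
            is.numeric(log_hr_regime),
            is.numeric(ltfu_informative_log_or),
            is.numeric(seed), length(seed) == 1L)
  structure(list(
    n_patients = as.integer(n_patients),
    max_months = as.integer(max_months),
    baseline_cd4_meanlog = baseline_cd4_meanlog,
    baseline_cd4_sdlog = baseline_cd4_sdlog,
    cd4_recovery_rate = cd4_recovery_rate,
    cd4_noise_sdlog = cd4_noise_sdlog,
    rna_suppression_probability = rna_suppression_probability,
    log_hazard_intercept = log_hazard_intercept,
    log_hr_off_prophylaxis = log_hr_off_prophylaxis,
    log_hr_regime = log_hr_regime,
    event_pcp_fraction = event_pcp_fraction,
    ltfu_monthly_probability = ltfu_monthly_probability,
    ltfu_informative_log_or = ltfu_informative_log_or,
    behaviour = behaviour,
    p_regime2 = p_regime2,
    adherence_probability = adherence_probability,
    random_stop_probability = random_stop_probability,
    seed = as.integer(seed)), class = "cohort_config")
}

#' True marginal hazard ratio of the simulated regime contrast
#'
#' The ground truth the estimation pipeline must recover on cohorts with no
#' intercurrent-event censoring and no loss to follow-up.
#'
#' @param config a [cohort_config()].
#' @return `exp(log_hr_regime)`.
#' @export
true_marginal_hr <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  exp(config$log_hr_regime)
}

#' Simulate a longitudinal prophylaxis cohort
#'
#' Generates one record per patient per month with CD4 and HIV-RNA
#' trajectories, prophylaxis status driven by the configured behaviour,
#' a composite PcP-or-death event process and an (optionally informative)
#' loss-to-follow-up process.  Within a month the ordering is: labs are
#' measured, the prophylaxis state is set by the behaviour rule, then the
#' event is drawn, then (if event-free) LTFU.  Exactly one terminal state per
#' patient: event, LTFU (`ltfu_after = TRUE` on the last record), or
#' administrative end at `max_months` records.
#'
#' Reproducible: the same config (including seed) gives byte-identical
#' output, and per-patient substreams mean patient `i`'s trajectory does not
#' depend on `n_patients`.
#'
#' @param config a [cohort_config()].
#' @return Data frame with columns `patient_id`, `month`, `cd4`, `rna`,
#'   `on_prophylaxis`, `on_cart`, `event_pcp`, `event_death`, `ltfu_after`,
#'   plus `behaviour_regime` (1, 2 or `NA`; the latent strategy — kept
#'   in memory for validation, not part of the on-disk schema written by
#'   [write_cohort()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  # per-patient column accumulators; one data.frame built at the end
  acc <- list(patient_id = vector("list", cfg$n_patients),
              month = vector("list", cfg$n_patients),
              cd4 = vector("list", cfg$n_patients),
              rna = vector("list", cfg$n_patients),
              on_prophylaxis = vector("list", cfg$n_patients),
              event_pcp = vector("list", cfg$n_patients),
              event_death = vector("list", cfg$n_patients),
              ltfu_after = vector("list", cfg$n_patients),
              behaviour_regime = vector("list", cfg$n_patients))
  regimes <- list(regime_cd4(), regime_rna())
  for (i in seq_len(cfg$n_patients)) {
    set.seed(substream_seed(cfg$seed, i))
    m <- cfg$max_months
    t <- seq_len(m) - 1L

    beh_regime <- switch(cfg$behaviour,
      regime1 = 1L, regime2 = 2L,
      mixture = if (runif(1) < cfg$p_regime2) 2L else 1L,
      random_stop = NA_integer_)

    cd4_0 <- exp(rnorm(1, cfg$baseline_cd4_meanlog, cfg$baseline_cd4_sdlog))
    cd4_mean <- pmin(cd4_0 + cfg$cd4_recovery_rate * t, 800)
    cd4 <- round(cd4_mean * exp(rnorm(m, 0, cfg$cd4_noise_sdlog)))
    cd4 <- pmax(cd4, 1)

    # unsuppressed until the first month (>= 1) a per-month suppression draw
    # fires; suppression is absorbing
    u_supp <- runif(m)
    supp_at <- which(u_supp < cfg$rna_suppression_probability & t >= 1L)[1]
    suppressed <- if (is.na(supp_at)) rep(FALSE, m) else t >= t[supp_at]
    rna_high <- round(10^(4.7 + rnorm(m, 0, 0.3)))
    rna <- ifelse(suppressed, 50, pmax(rna_high, 500))

    on_proph <- if (cfg$behaviour == "random_stop") {
      stop_at <- which(runif(m) < cfg$random_stop_probability)[1]
      if (is.na(stop_at)) rep(TRUE, m) else t < t[stop_at]
    } else {
      req <- required_prophylaxis(cd4, rna, regimes[[beh_regime]])
      if (cfg$adherence_probability >= 1) req
      else {
        # lagged adherence: conform to the required state with prob
        # `adherence_probability`, else carry last month's state
        conform <- runif(m) < cfg$adherence_probability
        obs <- logical(m)
        obs[1] <- req[1]
        if (m > 1L) for (s in 2:m)
          obs[s] <- if (conform[s]) req[s] else obs[s - 1L]
        obs
      }
    }

    off <- !on_proph
    regime2_beh <- as.integer(identical(beh_regime, 2L))
    p_event <- expit(cfg$log_hazard_intercept +
                     cfg$log_hr_off_prophylaxis * off +
                     cfg$log_hr_regime * regime2_beh)
    p_ltfu <- if (cfg$ltfu_monthly_probability == 0) rep(0, m)
              else expit(logit(cfg$ltfu_monthly_probability) +
                         cfg$ltfu_informative_log_or * off)

    u_event <- runif(m); u_ltfu <- runif(m); u_type <- runif(m)
    ev_at <- which(u_event < p_event)[1]
    lt_at <- which(u_ltfu < p_ltfu)[1]
    # event takes precedence over LTFU in the same month
    if (!is.na(ev_at) && !is.na(lt_at) && lt_at >= ev_at) lt_at <- NA
    last <- min(ev_at, lt_at, m, na.rm = TRUE)

    keep <- seq_len(last)
    ev_pcp <- ev_death <- rep(FALSE, last)
    ltfu_after <- rep(FALSE, last)
    if (!is.na(ev_at) && ev_at == last) {
      if (u_type[ev_at] < cfg$event_pcp_fraction) ev_pcp[last] <- TRUE
      else ev_death[last] <- TRUE
    } else if (!is.na(lt_at) && lt_at == last) {
      ltfu_after[last] <- TRUE
    }
    acc$patient_id[[i]] <- rep.int(sprintf("P%06d", i), last)
    acc$month[[i]] <- t[keep]
    acc$cd4[[i]] <- cd4[keep]
    acc$rna[[i]] <- rna[keep]
    acc$on_prophylaxis[[i]] <- on_proph[keep]
    acc$event_pcp[[i]] <- ev_pcp
    acc$event_death[[i]] <- ev_death
    acc$ltfu_after[[i]] <- ltfu_after
    acc$behaviour_regime[[i]] <- rep.int(beh_regime, last)
  }
  cols <- lapply(acc, function(x) unlist(x, use.names = FALSE))
  res <- data.frame(
    patient_id = as.character(cols$patient_id),
    month = as.integer(cols$month),
    cd4 = as.numeric(cols$cd4),
    rna = as.numeric(cols$rna),
    on_prophylaxis = as.logical(cols$on_prophylaxis),
    on_cart = rep(TRUE, length(cols$month)),
    event_pcp = as.logical(cols$event_pcp),
    event_death = as.logical(cols$event_death),
    ltfu_after = as.logical(cols$ltfu_after),
    behaviour_regime = as.integer(cols$behaviour_regime),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Read/write the long-format cohort table
#'
#' Comma-separated text with a header row and one visit record per line; the
#' column set is the input contract of [screen_eligibility()] and
#' [clone_and_follow()].
#'
#' @param visits cohort data frame (extra in-memory columns such as
#'   `behaviour_regime` are dropped on write).
#' @param path file path.
#' @return `read_cohort()` returns the cohort data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(visits, path) {
  cols <- c("patient_id", "month", "cd4", "rna", "on_prophylaxis",
            "on_cart", "event_pcp", "event_death", "ltfu_after")
  check_cohort_table(visits)
  write.csv(visits[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  visits <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("on_prophylaxis", "on_cart", "event_pcp", "event_death",
                "ltfu_after"))
    if (col %in% names(visits)) visits[[col]] <- as.logical(visits[[col]])
  check_cohort_table(visits)
  visits
}
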