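#' Eligibility configuration for the emulated trial
#'
#' Defaults encode the case-study entry criteria on the synthetic schema:
#' on combination antiretroviral therapy, currently taking PcP prophylaxis
#' (the target population is people taking prophylaxis, so both stopping
#' regimes are applicable), and CD4 below the recommendation threshold of
#' 200 cells/uL (prophylaxis "in line with existing recommendations").
#' Calendar-window and age criteria of the original study have no analogue in
#' the synthetic schema; an arbitrary extra predicate on the visit row can be
#' supplied for bespoke cohorts.
#'
#' @param require_cart require `on_cart` at time 0.
#' @param require_prophylaxis require `on_prophylaxis` at time 0.
#' @param max_cd4 require `cd4 < max_cd4` at time 0 (`Inf` disables).
#' @param extra optional `function(visits_row) -> logical` evaluated per row.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(require_cart = TRUE,
                                 require_prophylaxis = TRUE,
                                 max_cd4 = 200,
                                 extra = NULL) {
  check_flag(require_cart, "require_cart")
  check_flag(require_prophylaxis, "require_prophylaxis")
  stopifnot(is.numeric(max_cd4), is.null(extra) || is.function(extra))
  structure(list(require_cart = require_cart,
                 require_prophylaxis = require_prophylaxis,
                 max_cd4 = max_cd4, extra = extra),
            class = "eligibility_criteria")
}

#' Screen eligibility and set time zero
#'
#' Time 0 of the emulated trial is the first visit at which a patient meets
#' all eligibility criteria simultaneously; patients never meeting them are
#' absent from the result.
#'
#' @param visits cohort table (see [simulate_cohort()] for the schema),
#'   sorted by patient and month with no duplicate (patient, month) records.
#' @param criteria an [eligibility_criteria()].
#' @return Named integer vector mapping `patient_id` to the time-0 month.
#' @export
screen_eligibility <- function(visits, criteria = eligibility_criteria()) {
  check_cohort_table(visits)
  if (nrow(visits) == 0L)
    return(setNames(integer(0), character(0)))
  ok <- rep(TRUE, nrow(visits))
  if (criteria$require_cart) ok <- ok & visits$on_cart
  if (criteria$require_prophylaxis) ok <- ok & visits$on_prophylaxis
  ok <- ok & visits$cd4 < criteria$max_cd4
  if (!is.null(criteria$extra)) ok <- ok & vapply(
    seq_len(nrow(visits)), function(r) isTRUE(criteria$extra(visits[r, ])),
    logical(1))
  hit <- visits[ok, c("patient_id", "month")]
  if (nrow(hit) == 0L) return(setNames(integer(0), character(0)))
  first <- tapply(hit$month, hit$patient_id, min)
  setNames(as.integer(first), names(first))
}

#' Clone eligible patients into both regimes and censor
#'
#' The clone-censor step of clone-censor-weight: every eligible patient is
#' duplicated at their time 0 and assigned to both stopping regimes; each
#' clone's follow-up is truncated at the earliest of the composite event,
#' loss to follow-up, the first month of non-compliance with the assigned
#' regime (the intercurrent event, `censored_ice`), or the administrative
#' horizon.  Months are re-indexed so time 0 maps to month 0.  When several
#' terminal causes coincide in a month the precedence is event, then ICE
#' censoring, then LTFU.  Loss to follow-up must be flagged explicitly
#' (`ltfu_after`); records that simply end early (a patient entering the
#' cohort late relative to its administrative close) count as administrative
#' end, not LTFU.
#'
#' @param visits cohort table.
#' @param time0_map named vector from [screen_eligibility()].
#' @param regimes list of two [regime_spec()]s (default regime 1 = CD4-guided,
#'   regime 2 = suppression-guided).
#' @param grace compliance grace period in months (see [compliance_status()]).
#' @param horizon administrative end: clone months run 0..`horizon - 1`
#'   (default 60).
#' @return Data frame of clone-months: `patient_id`, `clone_arm`, `month`,
#'   `cd4`, `rna`, `on_prophylaxis`, `event`, `event_pcp`, `event_death`,
#'   `censored_ice`, `censored_ltfu`, `admin_end`, `imputed` (all `FALSE`
#'   here; set by the imputation module).
#' @export
clone_and_follow <- function(visits, time0_map,
                             regimes = list(regime_cd4(), regime_rna()),
                             grace = 1L, horizon = 60L) {
  check_cohort_table(visits)
  stopifnot(length(regimes) == 2L,
            inherits(regimes[[1]], "regime_spec"),
            inherits(regimes[[2]], "regime_spec"))
  if (length(time0_map) == 0L) return(empty_clone_table())
  pieces <- vector("list", 2L * length(time0_map))
  k <- 0L
  split_visits <- split(visits, visits$patient_id)
  for (pid in names(time0_map)) {
    pv <- split_visits[[pid]]
    if (is.null(pv) || !any(pv$month == time0_map[[pid]]))
      stop_ccw("patient ", pid, " has no visit record at time 0")
    pv <- pv[pv$month >= time0_map[[pid]], , drop = FALSE]
    pv$month <- pv$month - time0_map[[pid]]
    pv <- pv[pv$month < horizon, , drop = FALSE]
    for (arm in 1:2) {
      k <- k + 1L
      pieces[[k]] <- follow_one_clone(pv, arm, regimes[[arm]], grace,
                                      horizon)
    }
  }
  bind_clone_pieces(pieces)
}

bind_clone_pieces <- function(pieces) {
  one <- function(col, cast) cast(unlist(lapply(pieces, `[[`, col),
                                        use.names = FALSE))
  res <- data.frame(
    patient_id = one("patient_id", as.character),
    clone_arm = one("clone_arm", as.integer),
    month = one("month", as.integer),
    cd4 = one("cd4", as.numeric),
    rna = one("rna", as.numeric),
    on_prophylaxis = one("on_prophylaxis", as.logical),
    event = one("event", as.logical),
    event_pcp = one("event_pcp", as.logical),
    event_death = one("event_death", as.logical),
    censored_ice = one("censored_ice", as.logical),
    censored_ltfu = one("censored_ltfu", as.logical),
    admin_end = one("admin_end", as.logical),
    imputed = one("imputed", as.logical),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

empty_clone_table <- function() {
  data.frame(patient_id = character(), clone_arm = integer(),
             month = integer(), cd4 = numeric(), rna = numeric(),
             on_prophylaxis = logical(), event = logical(),
             event_pcp = logical(), event_death = logical(),
             censored_ice = logical(), censored_ltfu = logical(),
             admin_end = logical(), imputed = logical(),
             stringsAsFactors = FALSE)
}

follow_one_clone <- function(pv, arm, regime, grace, horizon) {
  n <- nrow(pv)
  comp <- compliance_status(pv, regime, grace = grace)
  ev_at <- which(pv$event_pcp | pv$event_death)[1]
  lt_at <- which(pv$ltfu_after)[1]
  ice_at <- if (is.na(comp$ice_month)) NA_integer_
            else comp$ice_month + 1L  # row index
  last <- min(ev_at, lt_at, ice_at, n, na.rm = TRUE)
  rows <- seq_len(last)
  event <- rep(FALSE, last); c_ice <- rep(FALSE, last)
  c_lt <- rep(FALSE, last); adm <- rep(FALSE, last)
  if (!is.na(ev_at) && ev_at == last) event[last] <- TRUE
  else if (!is.na(ice_at) && ice_at == last) c_ice[last] <- TRUE
  else if (!is.na(lt_at) && lt_at == last) c_lt[last] <- TRUE
  else adm[last] <- TRUE
  list(patient_id = pv$patient_id[rows], clone_arm = rep.int(arm, last),
       month = pv$month[rows], cd4 = pv$cd4[rows], rna = pv$rna[rows],
       on_prophylaxis = pv$on_prophylaxis[rows],
       event = event,
       event_pcp = pv$event_pcp[rows] & event,
       event_death = pv$event_death[rows] & event,
       censored_ice = c_ice, censored_ltfu = c_lt, admin_end = adm,
       imputed = rep.int(FALSE, last))
}

#' Collapse a behaviour-assigned cohort to a randomized single-clone trial
#'
#' In a simulated world where every patient follows an assigned stopping
#' regime exactly (`behaviour = "mixture"`) and never drops out, cloning and
#' censoring are identity operations: the clone matching the patient's own
#' strategy is never censored and the cross-arm clone carries no additional
#' information.  This helper keeps only the matching clone per patient,
#' yielding the person-month table of the randomized trial the emulation
#' targets — the ground-truth benchmark for parameter recovery.
#'
#' @param clone_months output of [clone_and_follow()].
#' @param visits the simulated cohort (must carry `behaviour_regime`).
#' @return Clone-month table restricted to each patient's own-strategy clone.
#' @export
as_randomized_trial <- function(clone_months, visits) {
  if (!"behaviour_regime" %in% names(visits))
    stop_ccw("`visits` lacks a behaviour_regime column; ",
             "simulate with behaviour = \"mixture\"")
  beh <- visits$behaviour_regime[!duplicated(visits$patient_id)]
  names(beh) <- visits$patient_id[!duplicated(visits$patient_id)]
  if (anyNA(beh[unique(clone_months$patient_id)]))
    stop_ccw("behaviour_regime is NA for some patients (random_stop ",
             "behaviour has no assigned regime)")
  keep <- clone_months$clone_arm == beh[clone_months$patient_id]
  res <- clone_months[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
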