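#' Prophylaxis-stopping regime specifications
#'
#' A regime is a deterministic treatment strategy saying, at each monthly
#' visit, whether PcP prophylaxis is required to be on or off given the lab
#' history.  Two regimes are built in:
#'
#' * **Regime 1** (current recommendation, CD4-driven): continue prophylaxis
#'   while CD4 < 200 cells/uL; stop once CD4 has been above 200 for more than
#'   3 consecutive monthly records (i.e. the stopping condition first fires at
#'   the 4th consecutive record above threshold).
#' * **Regime 2** (experimental, suppression-driven): continue prophylaxis
#'   while HIV RNA > 400 copies/ml; stop once viral suppression is confirmed
#'   by two consecutive measurements below 400 copies/ml.
#'
#' With `restart = TRUE` (the default) a regime re-requires prophylaxis when
#' its continuation condition reactivates (CD4 falls back below 200 / RNA
#' rebounds above 400).
#'
#' @param regime_id 1 or 2.
#' @param lab `"cd4"` or `"rna"`.
#' @param threshold lab threshold (cells/uL for CD4, copies/ml for RNA).
#' @param confirmation number of consecutive qualifying records required
#'   before stopping is mandated (4 for regime 1's "> 3 months", 2 for regime
#'   2's confirmed suppression).
#' @param restart logical; re-require prophylaxis after a rebound.
#' @return An object of class `regime_spec`.
#' @examples
#' regime_cd4()
#' regime_rna()
#' @export
regime_spec <- function(regime_id, lab, threshold, confirmation,
                        restart = TRUE) {
  stopifnot(regime_id %in% c(1L, 2L), lab %in% c("cd4", "rna"),
            is.numeric(threshold), threshold > 0,
            is.numeric(confirmation), confirmation >= 1)
  check_flag(restart, "restart")
  structure(list(regime_id = as.integer(regime_id), lab = lab,
                 threshold = threshold,
                 confirmation = as.integer(confirmation),
                 restart = restart),
            class = "regime_spec")
}

#' @rdname regime_spec
#' @export
regime_cd4 <- function(restart = TRUE) {
  regime_spec(1L, "cd4", 200, 4L, restart = restart)
}

#' @rdname regime_spec
#' @export
regime_rna <- function(restart = TRUE) {
  regime_spec(2L, "rna", 400, 2L, restart = restart)
}

#' @export
print.regime_spec <- function(x, ...) {
  rule <- if (x$lab == "cd4") {
    sprintf("stop once CD4 > %g for %d consecutive monthly records",
            x$threshold, x$confirmation)
  } else {
    sprintf("stop once %d consecutive HIV-RNA measurements < %g",
            x$confirmation, x$threshold)
  }
  cat(sprintf("<regime_spec %d> %s (restart %s)\n", x$regime_id, rule,
              if (x$restart) "on" else "off"))
  invisible(x)
}

#' Required prophylaxis state under a regime
#'
#' Evaluates a regime's deterministic strategy along a monthly lab history:
#' `TRUE` where prophylaxis is required on, `FALSE` where the stopping rule
#' has fired (and, with `restart`, not been reset by a rebound).
#'
#' For the CD4 regime the qualifying condition is `cd4 > threshold`; for the
#' RNA regime it is `rna < threshold`.  Stopping is required from the month
#' of the `confirmation`-th consecutive qualifying record onward.
#'
#' @param cd4,rna numeric vectors, one entry per consecutive month.
#' @param regime a [regime_spec()].
#' @return Logical vector, same length as the input.
#' @export
required_prophylaxis <- function(cd4, rna, regime) {
  n <- length(cd4)
  stopifnot(length(rna) == n)
  if (n == 0L) return(logical(0))
  qual <- if (regime$lab == "cd4") cd4 > regime$threshold
          else rna < regime$threshold
  qual[is.na(qual)] <- FALSE
  run <- integer(n)
  run[1] <- as.integer(qual[1])
  if (n > 1L) for (t in 2:n) run[t] <- if (qual[t]) run[t - 1L] + 1L else 0L
  if (regime$restart) {
    run < regime$confirmation
  } else {
    # once the rule has fired, prophylaxis stays off
    fired <- cumsum(run >= regime$confirmation) > 0L
    !fired
  }
}

#' Compliance of an observed prophylaxis history with a regime
#'
#' Compares the observed monthly prophylaxis states of one clone with the
#' states the assigned regime requires.  A grace period excuses *lagging*: an
#' observed state discordant with the current requirement is still compliant
#' if it matches a state the regime required within the previous `grace`
#' months.  Taking a state the regime did not recently require (e.g. stopping
#' after a single suppressed RNA measurement under regime 2) is an immediate
#' intercurrent event.
#'
#' @param history data frame of one clone's consecutive months with columns
#'   `cd4`, `rna`, `on_prophylaxis`.
#' @param regime a [regime_spec()].
#' @param grace non-negative integer, months of allowed lag (default 1).
#' @return List with `required` (logical vector), `compliant` (logical
#'   vector, `FALSE` from the first violation onward) and `ice_month` (0-based
#'   month of first non-compliance, or `NA` if always compliant).
#' @export
compliance_status <- function(history, regime, grace = 1L) {
  stopifnot(nrow(history) >= 1L, grace >= 0L)
  req <- required_prophylaxis(history$cd4, history$rna, regime)
  obs <- as.logical(history$on_prophylaxis)
  n <- length(req)
  ok <- logical(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - grace)
    ok[t] <- obs[t] %in% req[lo:t]
  }
  ice <- which(!ok)[1]
  list(required = req,
       compliant = cumsum(!ok) == 0L,
       ice_month = if (is.na(ice)) NA_integer_ else ice - 1L)
}
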