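# Hand-scripted cohort fixtures, built in code.

# One patient's visit block from compact vectors; scalars are recycled.
make_patient <- function(id, cd4, rna, proph = TRUE, cart = TRUE,
                         pcp_month = NA, death_month = NA, ltfu_month = NA) {
  n <- max(length(cd4), length(rna), length(proph))
  month <- seq_len(n) - 1L
  v <- data.frame(patient_id = id, month = month,
                  cd4 = rep_len(cd4, n), rna = rep_len(rna, n),
                  on_prophylaxis = rep_len(proph, n),
                  on_cart = rep_len(cart, n),
                  event_pcp = month == (pcp_month %||% -1),
                  event_death = month == (death_month %||% -1),
                  ltfu_after = month == (ltfu_month %||% -1),
                  stringsAsFactors = FALSE)
  v
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

bind_patients <- function(...) {
  v <- do.call(rbind, list(...))
  v[order(v$patient_id, v$month), ]
}

# A clone-month table built directly (bypassing the emulator) for fits on
# controlled event/censoring frequencies.
make_clone_table <- function(n_per_arm, events_per_arm, month = 0L,
                             weight = 1) {
  arm <- rep(1:2, each = n_per_arm)
  ev <- unlist(lapply(events_per_arm, function(k)
    c(rep(TRUE, k), rep(FALSE, n_per_arm - k))))
  data.frame(patient_id = sprintf("C%05d", seq_along(arm)),
             clone_arm = arm, month = month, cd4 = 150, rna = 50,
             on_prophylaxis = TRUE, event = ev, event_pcp = ev,
             event_death = FALSE, censored_ice = FALSE,
             censored_ltfu = FALSE, admin_end = !ev, imputed = FALSE,
             weight = weight, stringsAsFactors = FALSE)
}

# Default quick simulator settings used across tests (small but non-trivial).
quick_config <- function(...) {
  cohort_config(n_patients = 250, seed = 11,
                ltfu_monthly_probability = 2e-3, ...)
}
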