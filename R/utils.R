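# internal helpers

expit <- stats::plogis
logit <- stats::qlogis

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ccw <- function(..., call. = FALSE) stop(..., call. = call.)

check_prob <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 || (!allow_zero && x == 0)) {
    stop_ccw(sprintf("`%s` must be a probability in [0, 1], got %s",
                     name, format(x)))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_ccw(sprintf("`%s` must be TRUE or FALSE", name))
  invisible(x)
}

# Deterministic per-patient substream seed: changing n_patients must not
# reshuffle earlier patients' trajectories.  Kept below 2^31.
substream_seed <- function(master_seed, i) {
  (as.double(master_seed %% 1000003L) * 69069 + i * 2654435761) %%
    2147483647
}

# Validate the long-format cohort table (sorted, consecutive months, flags).
check_cohort_table <- function(visits) {
  need <- c("patient_id", "month", "cd4", "rna", "on_prophylaxis",
            "on_cart", "event_pcp", "event_death", "ltfu_after")
  missing <- setdiff(need, names(visits))
  if (length(missing))
    stop_ccw("cohort table is missing columns: ",
             paste(missing, collapse = ", "))
  key <- paste(visits$patient_id, visits$month)
  if (anyDuplicated(key))
    stop_ccw("duplicated (patient_id, month) records in cohort table")
  ord <- order(visits$patient_id, visits$month)
  if (is.unsorted(ord) && !identical(ord, seq_len(nrow(visits))))
    stop_ccw("cohort table must be sorted by patient_id then month")
  invisible(visits)
}
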