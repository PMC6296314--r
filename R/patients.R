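#' Patient records for a dose-finding trial
#'
#' A patient record carries the assigned dose level, entry time, the event
#' times to first moderate (grade >= 2) toxicity and to first DLT in cycles
#' since entry (NA if the event has not occurred by the end of the window),
#' and the current censored state: follow-up `c` (capped at `M`) and the
#' censored ordinal outcome `Y` with `Y = 2` iff `t_dlt <= c`, `Y = 1` iff
#' `t_mt <= c < t_dlt` (or no DLT), else `Y = 0`.
#'
#' @param dose_index integer dose levels assigned.
#' @param entry_time entry times in cycles since trial start.
#' @param t_mt,t_dlt event times in cycles since entry, `NA` for no event;
#'   when both occur, `t_mt <= t_dlt`.
#' @param now current trial time used to initialise `c` and `y`
#'   (default: all follow-up complete).
#' @param M assessment window in cycles.
#' @return a data frame of class `patient_records` with columns
#'   `dose_index`, `entry_time`, `t_mt`, `t_dlt`, `c`, `y`.
#' @export
patient_records <- function(dose_index, entry_time = 0, t_mt = NA_real_,
                            t_dlt = NA_real_, now = Inf, M = 6) {
  n <- length(dose_index)
  df <- data.frame(dose_index = as.integer(dose_index),
                   entry_time = rep_len(as.numeric(entry_time), n),
                   t_mt = rep_len(as.numeric(t_mt), n),
                   t_dlt = rep_len(as.numeric(t_dlt), n),
                   c = rep(NA_real_, n), y = rep(NA_integer_, n))
  bad <- !is.na(df$t_mt) & !is.na(df$t_dlt) & df$t_mt > df$t_dlt
  if (any(bad)) stop("t_mt must not exceed t_dlt when both are present")
  class(df) <- c("patient_records", "data.frame")
  update_followups(df, now = now, M = M)
}

#' Update follow-up and censored outcomes at the current trial time
#'
#' Recomputes each enrolled patient's follow-up `c = min(now - entry, M)`
#' and censored outcome `Y` from the stored event times.  Events are
#' observed when their time since entry does not exceed the current
#' follow-up.
#'
#' @param patients a [patient_records()] data frame.
#' @param now current trial time in cycles; must be at least every entry time.
#' @param M assessment window in cycles.
#' @return the updated `patient_records` data frame.
#' @export
update_followups <- function(patients, now, M = 6) {
  if (nrow(patients) == 0L) return(patients)
  if (any(now < patients$entry_time))
    stop("'now' precedes the entry time of an enrolled patient")
  cc <- pmin(now - patients$entry_time, M)
  cc[abs(cc - M) < 1e-9] <- M  # guard float noise in continuous entry times
  dlt_seen <- !is.na(patients$t_dlt) & patients$t_dlt <= cc
  mt_seen <- !is.na(patients$t_mt) & patients$t_mt <= cc
  patients$c <- cc
  patients$y <- ifelse(dlt_seen, 2L, ifelse(mt_seen, 1L, 0L))
  patients
}
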