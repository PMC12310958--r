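#' Compute the seven time-related features
#'
#' For each session (time-step) of each patient, derives: `date_diff` (days
#' since the patient's first session), `date_diff_session` (days since the
#' previous time-step; 0 for the first and for same-date successors),
#' `remaining_day_of_therapy` (a counter declining over time-steps, L..1),
#' `number_of_sessions` (rounds of this game averaged into this session),
#' `total_sessions_day` (sessions sharing this date), `total_sessions_incr`
#' (running count of sessions up to and including this date) and
#' `automode_sessions` (automode rounds recorded for this date).
#'
#' `remaining_day_of_therapy` depends on the series length, so it must be
#' recomputed after the series is shrunk to the fixed grid; the pipeline does
#' this automatically.
#'
#' @param sessions Session data frame (one or more patients), chronologically
#'   ordered within each patient.
#' @param automode_counts Data frame `(patient_id, date, n_automode)` from
#'   [exclude_automode_rounds()]; may be `NULL` for all-zero counts.
#' @return The input with the seven time-feature columns appended.
#' @export
compute_time_features <- function(sessions, automode_counts = NULL) {
  out <- sessions
  tf <- matrix(0, nrow = nrow(sessions), ncol = 7,
               dimnames = list(NULL, time_feature_names()))
  for (pid in unique(sessions$patient_id)) {
    rows <- which(sessions$patient_id == pid)
    d <- as.integer(as.Date(sessions$date[rows]))
    if (is.unsorted(d)) stop("sessions of patient ", pid,
                             " are not chronologically ordered", call. = FALSE)
    d <- d - d[1]
    L <- length(rows)
    date_diff <- d
    date_diff_session <- c(0L, diff(d))
    remaining <- L - seq_len(L) + 1L
    n_sessions <- sessions$n_rounds[rows]
    tot_day <- as.integer(table(d)[as.character(d)])
    tot_incr <- vapply(d, function(di) sum(d <= di), integer(1))
    auto <- rep(0L, L)
    if (!is.null(automode_counts)) {
      ac <- automode_counts[automode_counts$patient_id == pid, , drop = FALSE]
      m <- match(sessions$date[rows], ac$date)
      auto[!is.na(m)] <- ac$n_automode[m[!is.na(m)]]
    }
    tf[rows, ] <- cbind(date_diff, date_diff_session, remaining, n_sessions,
                        tot_day, tot_incr, auto)
  }
  out[colnames(tf)] <- as.data.frame(tf)
  out
}
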