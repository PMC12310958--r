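#' Remove automode rounds, keeping count of them
#'
#' Rounds played in automode (the robot moves the patient's arm passively)
#' carry no active-motion information and are excluded from the analysis,
#' but their number per patient-day is retained as an input feature.
#'
#' @param rounds Data frame of game rounds with at least `patient_id`,
#'   `date`, `automode` columns.
#' @return List with `rounds` (active rounds only) and `automode_counts`, a
#'   data frame `(patient_id, date, n_automode)` covering every patient-date
#'   seen in the input (zero rows included).
#' @export
exclude_automode_rounds <- function(rounds) {
  stopifnot(all(c("patient_id", "date", "automode") %in% names(rounds)))
  key <- interaction(rounds$patient_id, rounds$date, drop = TRUE, sep = "\r")
  n_auto <- tapply(rounds$automode, key, sum)
  parts <- strsplit(names(n_auto), "\r", fixed = TRUE)
  counts <- data.frame(
    patient_id = vapply(parts, `[`, "", 1L),
    date = vapply(parts, `[`, "", 2L),
    n_automode = as.integer(n_auto),
    stringsAsFactors = FALSE
  )
  counts <- counts[order(counts$patient_id, counts$date), , drop = FALSE]
  rownames(counts) <- NULL
  active <- rounds[!rounds$automode, , drop = FALSE]
  rownames(active) <- NULL
  list(rounds = active, automode_counts = counts)
}

#' Average same-day rounds of a game into a session
#'
#' Most games are played several times per day; noise is reduced by
#' averaging the kinematic features of all rounds of the same game on the
#' same date. The resulting "session" is one time-step of the patient's
#' series. Robot parameter levels are attached per
#' [attach_robot_parameters()]; sessions are returned in chronological
#' order (stable within a date).
#'
#' @param rounds Data frame of active (non-automode) rounds.
#' @param feature_names Kinematic feature columns to average; defaults to
#'   every column after the fixed ones.
#' @return Data frame with one row per `(patient_id, date, game_id)`, the
#'   averaged features, the attached levels and `n_rounds`.
#' @export
average_rounds_to_sessions <- function(rounds, feature_names = NULL) {
  fixed <- c("patient_id", "date", "game_id", "automode",
             "stiffness", "weight", "viscosity")
  if (is.null(feature_names))
    feature_names <- setdiff(names(rounds), fixed)
  key <- interaction(rounds$patient_id, rounds$date, rounds$game_id,
                     drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(rounds)), key)
  out <- lapply(idx, function(i) {
    sub <- rounds[i, , drop = FALSE]
    vals <- vapply(feature_names, function(f) {
      v <- sub[[f]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    lev <- attach_robot_parameters(sub)
    row <- data.frame(
      patient_id = sub$patient_id[1], date = sub$date[1],
      game_id = sub$game_id[1],
      stiffness = lev[["stiffness"]], weight = lev[["weight"]],
      viscosity = lev[["viscosity"]],
      n_rounds = nrow(sub), stringsAsFactors = FALSE
    )
    row[feature_names] <- as.list(vals)
    row$.first_row <- min(i)
    row
  })
  sessions <- do.call(rbind, out)
  # chronological order; stable input order within a date
  sessions <- sessions[order(sessions$patient_id, sessions$date,
                             sessions$.first_row), , drop = FALSE]
  sessions$.first_row <- NULL
  rownames(sessions) <- NULL
  sessions
}

#' Attach robot parameter levels to an averaged session
#'
#' When multiple rounds are averaged into a session, each parameter is
#' assigned the nearest available value: if all rounds agree that level is
#' used; on conflict the level of the chronologically last round wins (the
#' therapist's most recent setting of the day); a round missing a parameter
#' inherits the temporally nearest round's value.
#'
#' @param rounds_of_session Data frame of the rounds being averaged, in time
#'   order, with `stiffness`, `weight`, `viscosity` columns.
#' @return Named character vector of the three levels.
#' @export
attach_robot_parameters <- function(rounds_of_session) {
  if (nrow(rounds_of_session) < 1L)
    stop("at least one round required", call. = FALSE)
  vapply(c("stiffness", "weight", "viscosity"), function(param) {
    v <- rounds_of_session[[param]]
    ok <- which(!is.na(v))
    if (length(ok) == 0L)
      stop("no round carries parameter '", param, "'", call. = FALSE)
    check_levels(v[ok], param)
    v[ok[length(ok)]]
  }, character(1))
}

#' Retain kinematic features shared by enough games
#'
#' A kinematic feature is kept only if the fraction of games whose feature
#' set contains it ("mutuality") exceeds the threshold; by default strictly
#' above 70%. The denominator is the configured number of games, a
#' dataset-level schema decision.
#'
#' @param sessions Session data frame (used only to verify features occur);
#'   may be `NULL` when masks alone define the schema.
#' @param game_feature_masks List of per-game feature-name vectors.
#' @param threshold Mutuality threshold (default 0.70, strict `>`).
#' @return Character vector of retained feature names, in canonical schema
#'   order (unknown features after the canonical ones, alphabetically).
#' @export
filter_features_by_mutuality <- function(sessions, game_feature_masks,
                                         threshold = 0.70) {
  if (!is.null(sessions) && nrow(sessions) == 0L)
    stop("empty session set", call. = FALSE)
  n_games <- length(game_feature_masks)
  feats <- unique(unlist(game_feature_masks))
  frac <- vapply(feats, function(f)
    sum(vapply(game_feature_masks, function(m) f %in% m, logical(1))) /
      n_games, numeric(1))
  kept <- feats[frac > threshold]
  canon <- kinematic_feature_names()
  c(canon[canon %in% kept], sort(setdiff(kept, canon)))
}

#' Fill missing kinematic values in a session table
#'
#' For each missing `(patient, date, game, feature)` value, the mean of the
#' feature over the patient's other sessions on the same date is used; when
#' no same-date value exists, the patient's most recent prior value is
#' carried forward (front-fill). If a feature has no prior value either, the
#' next available value is carried backward, and failing that 0 is used
#' (with a warning).
#'
#' @param sessions Session data frame, chronologically ordered per patient.
#' @param feature_names Features to complete.
#' @return The session data frame with no `NA` left in `feature_names`.
#' @export
fill_missing_values <- function(sessions, feature_names) {
  out <- sessions
  for (pid in unique(out$patient_id)) {
    rows <- which(out$patient_id == pid)
    sub <- out[rows, , drop = FALSE]
    for (f in feature_names) {
      v <- sub[[f]]
      miss <- which(is.na(v))
      if (length(miss) == 0L) next
      # pass 1: same-date mean over the patient's other sessions
      for (i in miss) {
        same_day <- v[sub$date == sub$date[i]]
        same_day <- same_day[!is.na(same_day)]
        if (length(same_day) > 0L) v[i] <- mean(same_day)
      }
      # pass 2: front-fill, then back-fill on what remains
      if (anyNA(v)) {
        for (i in which(is.na(v)))
          if (i > 1L && !all(is.na(v[1:(i - 1L)])))
            v[i] <- v[max(which(!is.na(v[1:(i - 1L)])))]
      }
      if (anyNA(v)) {
        for (i in rev(which(is.na(v))))
          if (i < length(v) && !all(is.na(v[(i + 1L):length(v)])))
            v[i] <- v[i + min(which(!is.na(v[(i + 1L):length(v)])))]
      }
      if (anyNA(v)) {
        warning("feature '", f, "' never observed for patient ", pid,
                "; filled with 0", call. = FALSE)
        v[is.na(v)] <- 0
      }
      out[[f]][rows] <- v
    }
  }
  out
}

#' Apply the two patient exclusion criteria
#'
#' A patient is retained only with (i) at least `min_attendances` distinct
#' therapy dates with an active session and (ii) all three post-treatment
#' clinical scores present. A patient failing both is counted once under the
#' missing-post-assessment reason.
#'
#' @param patients Patient table with `arat_t1`, `fma_t1`, `mi_t1`.
#' @param sessions Session data frame after automode exclusion.
#' @param min_attendances Minimum distinct dates (default 10, inclusive).
#' @return List with `patients`, `sessions` (retained only) and `report`, an
#'   `exclusion_report` with counts and per-patient reason codes.
#' @export
apply_patient_exclusions <- function(patients, sessions,
                                     min_attendances = 10L) {
  n_dates <- vapply(patients$patient_id, function(pid)
    length(unique(sessions$date[sessions$patient_id == pid])), integer(1))
  has_t1 <- !is.na(patients$arat_t1) & !is.na(patients$fma_t1) &
    !is.na(patients$mi_t1)
  reason <- rep("retained", nrow(patients))
  reason[n_dates < min_attendances] <- "too_few_attendances"
  reason[!has_t1] <- "no_post_assessment"  # takes precedence
  keep <- reason == "retained"
  report <- structure(list(
    n_input_patients = nrow(patients),
    n_excluded_no_post_assessment = sum(reason == "no_post_assessment"),
    n_excluded_too_few_attendances = sum(reason == "too_few_attendances"),
    n_retained = sum(keep),
    reasons = data.frame(patient_id = patients$patient_id, reason = reason,
                         n_dates = n_dates, stringsAsFactors = FALSE)
  ), class = "exclusion_report")
  kept_ids <- patients$patient_id[keep]
  list(
    patients = patients[keep, , drop = FALSE],
    sessions = sessions[sessions$patient_id %in% kept_ids, , drop = FALSE],
    report = report
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Patient exclusions: ", x$n_input_patients, " in, ", x$n_retained,
      " retained (", x$n_excluded_no_post_assessment,
      " missing post assessment, ", x$n_excluded_too_few_attendances,
      " with too few attendances)\n", sep = "")
  invisible(x)
}

#' Write an exclusion report as JSON
#'
#' @param report An `exclusion_report`.
#' @param path Output path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
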