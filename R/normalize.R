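#' Fit the normalization state on a training cohort
#'
#' All features are scaled to `[0, 1]` by division with fitted maxima:
#' demographics use cohort-wide maxima (latency on a log scale), kinematic
#' features use per-(game, feature) maxima so that the highest-performing
#' patients define the reference for each game scenario, time-related
#' features use each patient's own maxima, robot parameters and clinical
#' scales use their fixed level/scale maxima. The state stores every fitted
#' maximum, making each transform exactly invertible on in-range data.
#'
#' Maxima are fitted on training patients only; out-of-range values seen at
#' test time are clipped to `[0, 1]`.
#'
#' @param sessions Training session data frame (time features computed).
#' @param patients Training patient table.
#' @param feature_names Retained kinematic feature names.
#' @param n_games Number of games.
#' @return An object of class `normalization_state`.
#' @export
fit_normalizer <- function(sessions, patients, feature_names,
                           n_games = 7L) {
  guard <- function(m) {
    if (!is.finite(m) || m <= 0) 1 else m
  }
  kin_max <- matrix(1, nrow = n_games, ncol = length(feature_names),
                    dimnames = list(NULL, feature_names))
  for (g in seq_len(n_games)) {
    rows <- sessions$game_id == g
    for (f in feature_names) {
      v <- sessions[[f]][rows]
      v <- v[!is.na(v)]
      if (length(v) == 0L || max(v) <= 0) {
        if (length(v) > 0L)
          warning("all-zero feature '", f, "' for game ", g,
                  "; unit scale used", call. = FALSE)
        next
      }
      kin_max[g, f] <- max(v)
    }
  }
  tf_names <- time_feature_names()
  have_tf <- all(tf_names %in% names(sessions))
  time_max <- NULL
  if (have_tf) {
    time_max <- do.call(rbind, lapply(unique(sessions$patient_id),
                                      function(pid) {
      sub <- sessions[sessions$patient_id == pid, tf_names, drop = FALSE]
      data.frame(patient_id = pid,
                 t(vapply(sub, function(v) guard(max(v)), numeric(1))),
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
  }
  structure(list(
    age_max = guard(max(patients$age)),
    latency_logmax = guard(max(log1p(patients$latency_days))),
    kin_max = kin_max,
    time_max = time_max,
    robot_map = list(stiffness = c(Low = 1, Mid = 2, High = 3),
                     weight = c(Low = 1, Mid = 2, High = 3),
                     viscosity = c(Low = 1, High = 2)),
    scale_max = clinical_scale_max(),
    feature_names = feature_names,
    n_games = as.integer(n_games)
  ), class = "normalization_state")
}

#' @export
print.normalization_state <- function(x, ...) {
  cat("Normalization state: age max ", x$age_max, ", log-latency max ",
      round(x$latency_logmax, 3), ", ", nrow(x$kin_max), " games x ",
      ncol(x$kin_max), " kinematic maxima, ",
      if (is.null(x$time_max)) 0 else nrow(x$time_max),
      " patients with time-feature maxima\n", sep = "")
  invisible(x)
}

#' Normalize demographics of one patient
#'
#' Age is divided by the cohort maximum; gender (a 0/1 indicator) is
#' unchanged by division with its maximum; latency is transformed with
#' `log1p` and divided by the cohort maximum of `log1p(latency)`.
#'
#' @param record One-row patient data frame (or list) with `age`, `gender`,
#'   `latency_days`.
#' @param state A `normalization_state`.
#' @return Numeric vector `c(age, gender, latency)` in `[0, 1]` (clipped).
#' @export
normalize_demographics <- function(record, state) {
  v <- c(age = record$age / state$age_max,
         gender = as.numeric(record$gender),
         latency = log1p(record$latency_days) / state$latency_logmax)
  pmin(pmax(v, 0), 1)  # pmax(v, .) keeps the names
}

#' Normalize kinematic features of sessions
#'
#' Each value is divided by the training maximum fitted for its (game,
#' feature) pair; values above the maximum (possible at test time) are
#' clipped to 1.
#'
#' @param sessions Session data frame with `game_id` and the kinematic
#'   columns.
#' @param state A `normalization_state`.
#' @return The data frame with kinematic columns replaced by normalized
#'   values.
#' @export
normalize_kinematics <- function(sessions, state) {
  out <- sessions
  for (f in state$feature_names) {
    mx <- state$kin_max[out$game_id, f]
    out[[f]] <- pmin(1, pmax(0, out[[f]] / mx))
  }
  out
}

#' Map robot parameter levels to normalized values
#'
#' Levels are encoded ordinally (Low = 1, Mid = 2, High = 3; viscosity
#' Low = 1, High = 2) and divided by the level-set maximum, giving
#' stiffness/weight in `{1/3, 2/3, 1}` and viscosity in `{1/2, 1}`.
#'
#' @param levels Named character vector/list with `stiffness`, `weight`,
#'   `viscosity` (each may be a vector).
#' @return Named list (or vector for scalars) of normalized values.
#' @export
normalize_robot_params <- function(levels) {
  map <- list(stiffness = c(Low = 1, Mid = 2, High = 3),
              weight = c(Low = 1, Mid = 2, High = 3),
              viscosity = c(Low = 1, High = 2))
  out <- lapply(names(map), function(param) {
    x <- levels[[param]]
    check_levels(x, param)
    unname(map[[param]][x] / max(map[[param]]))
  })
  names(out) <- names(map)
  if (all(lengths(out) == 1L)) unlist(out) else out
}

#' Recover level class indices from normalized robot parameter values
#'
#' Exact inverse of the ordinal level mapping: a normalized value `v` of a
#' parameter with `K` levels maps back to class `round(v * K)`.
#'
#' @param values Numeric vector of normalized values.
#' @param param One of `"stiffness"`, `"weight"`, `"viscosity"`.
#' @param as_level If `TRUE` return level labels instead of 1-based indices.
#' @return Integer class indices (or level labels).
#' @export
invert_robot_params <- function(values, param, as_level = FALSE) {
  levs <- robot_level_sets()[[param]]
  k <- length(levs)
  idx <- as.integer(round(values * k))
  if (any(idx < 1L | idx > k))
    stop("normalized ", param, " value outside the level grid", call. = FALSE)
  if (as_level) levs[idx] else idx
}

#' Normalize the seven time-related features per patient
#'
#' Each time-related feature is divided by that patient's own maximum of the
#' feature, reflecting the patient's deviation from their planned schedule;
#' an all-zero feature stays zero (unit scale).
#'
#' @param series One patient's session data frame with the time-feature
#'   columns.
#' @param maxima Optional named numeric vector of the patient's maxima (e.g.
#'   from a fitted state); computed from `series` when `NULL`.
#' @return List with `series` (normalized) and `maxima` used.
#' @export
normalize_time_features <- function(series, maxima = NULL) {
  tf_names <- time_feature_names()
  if (is.null(maxima)) {
    maxima <- vapply(tf_names, function(f) {
      m <- max(series[[f]])
      if (!is.finite(m) || m <= 0) 1 else m
    }, numeric(1))
  }
  for (f in tf_names)
    series[[f]] <- pmin(1, pmax(0, series[[f]] / maxima[[f]]))
  list(series = series, maxima = maxima)
}

#' Normalize clinical scores to [0, 1] and back
#'
#' Divides ARAT, FMA and MI by their scale maxima (57, 66, 100);
#' [denormalize_clinical_scores()] multiplies back exactly.
#'
#' @param scores Named numeric vector/list with `arat`, `fma`, `mi`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
normalize_clinical_scores <- function(scores) {
  mx <- clinical_scale_max()
  out <- vapply(names(mx), function(s) {
    x <- as.numeric(scores[[s]])
    if (is.na(x) || x < 0 || x > mx[[s]])
      stop(s, " score out of bounds [0, ", mx[[s]], "]", call. = FALSE)
    x / mx[[s]]
  }, numeric(1))
  out
}

#' @rdname normalize_clinical_scores
#' @param values Named numeric vector in `[0, 1]` (`arat`, `fma`, `mi`).
#' @export
denormalize_clinical_scores <- function(values) {
  mx <- clinical_scale_max()
  vapply(names(mx), function(s) as.numeric(values[[s]]) * mx[[s]],
         numeric(1))
}

#' Serialize a normalization state to JSON
#'
#' @param state A `normalization_state`.
#' @param path Output path.
#' @export
write_normalizer <- function(state, path) {
  jsonlite::write_json(unclass(state), path, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
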