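#' Prepare a cohort: from raw round logs to harmonized session series
#'
#' Runs the full data-management chain on per-round logs: automode rounds are
#' excluded (their counts kept), same-day rounds of a game are averaged into
#' sessions, kinematic features below the mutuality threshold are dropped,
#' missing values are filled (same-date mean, then front-fill), the two
#' patient exclusion rules are applied, over-long series are shrunk to the
#' target grid, and the seven time-related features are computed on the
#' final series (so the declining therapy counter reflects the harmonized
#' length).
#'
#' Normalization is deliberately not part of this step: its maxima must be
#' fitted on training patients only, per cross-validation fold.
#'
#' @param rounds Per-round log data frame (see [simulate_cohort()] /
#'   [read_cohort_csv()] for the format).
#' @param patients Patient table.
#' @param game_feature_masks Per-game feature masks defining mutuality;
#'   defaults to [default_game_feature_masks()].
#' @param n_games Number of games (default 7).
#' @param target Harmonized series length (default 64).
#' @param mutuality_threshold Strict lower bound on the game-share of a
#'   retained feature (default 0.70).
#' @param min_attendances Minimum distinct active-session dates (default 10).
#' @param gap_tie Tie-break direction for [shrink_series()].
#' @return Object of class `prepared_cohort`: final `sessions` (with time
#'   features), retained `patients`, `automode_counts`, `features`
#'   (retained kinematic names), `report` (exclusions), `removals`
#'   (shrinking log) and the pipeline constants.
#' @export
prepare_cohort <- function(rounds, patients,
                           game_feature_masks = NULL,
                           n_games = 7L,
                           target = 64L,
                           mutuality_threshold = 0.70,
                           min_attendances = 10L,
                           gap_tie = "small") {
  if (is.null(game_feature_masks))
    game_feature_masks <- default_game_feature_masks(n_games)
  ex <- exclude_automode_rounds(rounds)
  sessions <- average_rounds_to_sessions(ex$rounds)
  retained <- filter_features_by_mutuality(sessions, game_feature_masks,
                                           mutuality_threshold)
  sessions <- fill_missing_values(sessions, retained)
  excl <- apply_patient_exclusions(patients, sessions, min_attendances)
  sessions <- excl$sessions
  out_sessions <- list(); removals <- list()
  for (pid in excl$patients$patient_id) {
    series <- sessions[sessions$patient_id == pid, , drop = FALSE]
    h <- harmonize_patient(series, target, gap_tie)
    out_sessions[[pid]] <- h$series
    if (nrow(h$removals) > 0L)
      removals[[pid]] <- cbind(patient_id = pid, h$removals)
  }
  final_sessions <- do.call(rbind, out_sessions)
  rownames(final_sessions) <- NULL
  final_sessions <- compute_time_features(final_sessions,
                                          ex$automode_counts)
  structure(list(
    sessions = final_sessions,
    patients = excl$patients,
    automode_counts = ex$automode_counts,
    features = retained,
    report = excl$report,
    removals = if (length(removals)) do.call(rbind, c(removals,
                                                      make.row.names = FALSE))
               else NULL,
    n_games = as.integer(n_games),
    target = as.integer(target)
  ), class = "prepared_cohort")
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat("Prepared cohort: ", nrow(x$patients), " patients, ",
      nrow(x$sessions), " sessions on a ", x$target, "-point grid, ",
      length(x$features), " kinematic features retained\n", sep = "")
  invisible(x)
}

#' Patient-level cross-validation folds
#'
#' Partitions patient ids into `k` near-equal folds, deterministically for a
#' given seed. The same fold plan is shared verbatim by the recurrent models
#' and the random-forest baselines so comparisons are paired.
#'
#' @param patient_ids Character vector of patient ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list of `k` character vectors.
#' @examples
#' make_cv_folds(sprintf("P%02d", 1:10), k = 5, seed = 42)
#' @export
make_cv_folds <- function(patient_ids, k = 5L, seed = 42L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > length(patient_ids))
    stop("k exceeds the number of patients", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  shuffled <- sample(patient_ids)
  assignment <- rep(seq_len(k), length.out = length(shuffled))
  folds <- split(shuffled, assignment)
  names(folds) <- paste0("fold", seq_len(k))
  structure(list(folds = folds, k = k, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Fold plan: ", x$k, " patient-level folds of sizes ",
      paste(lengths(x$folds), collapse = "/"), " (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}
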