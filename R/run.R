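#' Run the full pipeline end to end
#'
#' Convenience orchestration: simulate (or accept) a cohort, prepare it
#' (ingest, filter, fill, exclude, harmonize, time features), build the
#' shared patient-level fold plan, evaluate the outcome predictor and the
#' three difficulty recommenders against their baselines, and optionally
#' write the report files.
#'
#' @param cohort A `rehab_cohort` (from [simulate_cohort()] or
#'   [read_cohort_csv()]); if `NULL`, one is simulated from `sim`.
#' @param sim A [sim_config()] used when `cohort` is `NULL`.
#' @param k Number of cross-validation folds.
#' @param fold_seed Seed of the fold plan.
#' @param outcome_config An [outcome_model_config()].
#' @param difficulty_configs Named list of [difficulty_model_config()]s
#'   (default: the three tuned configurations).
#' @param with_rf Train random-forest baselines.
#' @param out_dir If non-`NULL`, write the evaluation report, exclusion
#'   report and normalizer-audit files there.
#' @return List with `cohort`, `prepared`, `folds`, `outcome` and
#'   `difficulty` evaluation objects.
#' @export
run_pipeline <- function(cohort = NULL, sim = sim_config(),
                         k = 5L, fold_seed = 42L,
                         outcome_config = outcome_model_config(),
                         difficulty_configs = NULL,
                         with_rf = TRUE, out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(sim)
  masks <- if (!is.null(cohort$config)) cohort$config$game_feature_masks
           else NULL
  n_games <- if (!is.null(cohort$config)) cohort$config$n_games else 7L
  prepared <- prepare_cohort(cohort$rounds, cohort$patients,
                             game_feature_masks = masks, n_games = n_games)
  folds <- make_cv_folds(prepared$patients$patient_id, k, fold_seed)
  outcome <- evaluate_outcome_cv(prepared, folds, outcome_config,
                                 with_rf = with_rf)
  difficulty <- evaluate_difficulty_cv(prepared, folds,
                                       configs = difficulty_configs,
                                       with_rf = with_rf)
  if (!is.null(out_dir)) {
    write_eval_report(outcome, difficulty, out_dir)
    write_exclusion_report(prepared$report,
                           file.path(out_dir, "exclusions.json"))
  }
  list(cohort = cohort, prepared = prepared, folds = folds,
       outcome = outcome, difficulty = difficulty)
}
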