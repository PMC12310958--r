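# Shared synthetic cohorts, built once per test run and cached.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, ...) {
  if (is.null(.cohort_cache[[key]])) {
    cfg <- sim_config(...)
    .cohort_cache[[key]] <- list(config = cfg, cohort = simulate_cohort(cfg))
  }
  .cohort_cache[[key]]
}

cached_prepared <- function(key, ...) {
  pkey <- paste0(key, ".prepared")
  if (is.null(.cohort_cache[[pkey]])) {
    cc <- cached_cohort(key, ...)
    .cohort_cache[[pkey]] <- prepare_cohort(
      cc$cohort$rounds, cc$cohort$patients,
      cc$config$game_feature_masks, cc$config$n_games)
  }
  .cohort_cache[[pkey]]
}

# Small default cohort most tests share.
small_prepared <- function() {
  cached_prepared("small", n_patients = 10, seed = 3)
}

small_tensor <- function() {
  if (is.null(.cohort_cache[["small.tensor"]])) {
    prep <- small_prepared()
    state <- fit_normalizer(prep$sessions, prep$patients, prep$features)
    .cohort_cache[["small.tensor"]] <-
      assemble_cohort_tensor(prep, state)
  }
  .cohort_cache[["small.tensor"]]
}

# Minimal hand-built session table: one patient, explicit dates/games.
toy_sessions <- function(pid = "P1", dates, games, n_rounds = 1L,
                         extra = list()) {
  d <- data.frame(
    patient_id = pid,
    date = format(as.Date("2024-01-01") + dates),
    game_id = games,
    stiffness = "Mid", weight = "Mid", viscosity = "Low",
    n_rounds = n_rounds,
    stringsAsFactors = FALSE
  )
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  d
}
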