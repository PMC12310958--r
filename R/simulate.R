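#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of [simulate_cohort()]. The defaults
#' describe a realistic robot-assisted upper-limb therapy programme: seven
#' serious games with partially overlapping kinematic feature sets, a few
#' game rounds per day over several therapy weeks, three-level stiffness and
#' weight, two-level viscosity set by a persistence-biased therapist policy,
#' occasional passively driven (automode) rounds, and discharge scores tied
#' to each patient's latent recovery trajectory.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   bit for bit.
#' @param days_range Length-2 integer range of distinct therapy dates per
#'   patient. The default (12, 30) combined with several games per day makes
#'   both the padding (< 64 time-steps) and shrinking (> 64) branches of the
#'   harmonizer occur in one cohort.
#' @param rounds_per_day_range Length-2 range of game rounds played per day.
#' @param n_games Number of serious games (default 7).
#' @param game_feature_masks Optional list of length `n_games`; element `g`
#'   names the kinematic features game `g` records. Defaults to
#'   [default_game_feature_masks()].
#' @param automode_prob_initial Probability that a round on the first therapy
#'   day runs in automode; the probability decays geometrically with
#'   `automode_decay` per day (passive use is most common early on).
#' @param automode_decay Per-day geometric decay of the automode probability.
#' @param recovery_rate_range Range of the per-day latent ability gain.
#' @param noise_sd Standard deviation of the multiplicative lognormal noise
#'   on kinematic values, and (scaled) of the additive noise on clinical
#'   scores. 0 gives a noiseless cohort.
#' @param therapist_persistence Probability that each robot parameter simply
#'   repeats the previous session's level.
#' @param escalation_threshold Latent-ability level above which the policy,
#'   when it does change a level, raises difficulty rather than lowers it.
#' @param t1_missing_prob Probability a patient drops out before the
#'   discharge assessment (all three post scores missing).
#' @param short_stay_prob Probability a patient attends fewer than 10 days
#'   (exercises the attendance exclusion rule).
#' @param feature_missing_prob Probability any recorded kinematic value is
#'   lost (exercises the missing-value fill).
#' @param driver_feature Optional name of one kinematic feature. When set,
#'   only this feature tracks the patient's latent ability; the remaining
#'   kinematic features are ability-independent noise. Used for
#'   explainability recovery experiments.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 60L,
                       seed = 1L,
                       days_range = c(12L, 30L),
                       rounds_per_day_range = c(3L, 8L),
                       n_games = 7L,
                       game_feature_masks = NULL,
                       automode_prob_initial = 0.3,
                       automode_decay = 0.8,
                       recovery_rate_range = c(0.005, 0.03),
                       noise_sd = 0.15,
                       therapist_persistence = 0.8,
                       escalation_threshold = 0.55,
                       t1_missing_prob = 0.05,
                       short_stay_prob = 0.05,
                       feature_missing_prob = 0.02,
                       driver_feature = NULL) {
  chk_count <- function(x, nm, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      stop("invalid sim_config field '", nm, "': must be a count >= ", min,
           call. = FALSE)
    as.integer(x)
  }
  chk_prob <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("invalid sim_config field '", nm, "': must be in [0, 1]",
           call. = FALSE)
    as.numeric(x)
  }
  chk_range <- function(x, nm, min = 0) {
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < min)
      stop("invalid sim_config field '", nm,
           "': must be (min, max) with min <= max", call. = FALSE)
    x
  }
  n_patients <- chk_count(n_patients, "n_patients")
  seed <- chk_count(seed, "seed", min = 0L)
  n_games <- chk_count(n_games, "n_games", min = 2L)
  days_range <- as.integer(chk_range(days_range, "days_range", min = 1))
  rounds_per_day_range <- as.integer(
    chk_range(rounds_per_day_range, "rounds_per_day_range", min = 1))
  recovery_rate_range <- chk_range(recovery_rate_range, "recovery_rate_range")
  if (length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0)
    stop("invalid sim_config field 'noise_sd': must be >= 0", call. = FALSE)
  if (is.null(game_feature_masks))
    game_feature_masks <- default_game_feature_masks(n_games)
  if (length(game_feature_masks) != n_games)
    stop("invalid sim_config field 'game_feature_masks': need one mask per game",
         call. = FALSE)
  all_feats <- unique(unlist(game_feature_masks))
  if (!is.null(driver_feature) &&
      !(driver_feature %in% kinematic_feature_names()))
    stop("invalid sim_config field 'driver_feature': unknown feature",
         call. = FALSE)
  cfg <- list(
    n_patients = n_patients,
    seed = seed,
    days_range = days_range,
    rounds_per_day_range = rounds_per_day_range,
    n_games = n_games,
    game_feature_masks = game_feature_masks,
    all_features = all_feats,
    automode_prob_initial = chk_prob(automode_prob_initial,
                                     "automode_prob_initial"),
    automode_decay = chk_prob(automode_decay, "automode_decay"),
    recovery_rate_range = as.numeric(recovery_rate_range),
    noise_sd = as.numeric(noise_sd),
    therapist_persistence = chk_prob(therapist_persistence,
                                     "therapist_persistence"),
    escalation_threshold = chk_prob(escalation_threshold,
                                    "escalation_threshold"),
    t1_missing_prob = chk_prob(t1_missing_prob, "t1_missing_prob"),
    short_stay_prob = chk_prob(short_stay_prob, "short_stay_prob"),
    feature_missing_prob = chk_prob(feature_missing_prob,
                                    "feature_missing_prob"),
    driver_feature = driver_feature
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-game kinematic feature masks
#'
#' Twelve core kinematic features are recorded by every game; four
#' (`params`, `workTanUserSelf`, `smoothness_force`, `smoothness_kin`) are
#' each missing from one game, giving them 6/7 mutuality (retained by the
#' > 70% filter but creating realistic missingness), and two decoy features
#' (`gripVariance`, `pauseCount`) appear in only three games (3/7 mutuality,
#' dropped by the filter).
#'
#' @param n_games Number of games.
#' @return List of `n_games` character vectors.
#' @export
default_game_feature_masks <- function(n_games = 7L) {
  kin <- kinematic_feature_names()
  partial <- c("params", "workTanUserSelf", "smoothness_force",
               "smoothness_kin")
  core <- setdiff(kin, partial)
  masks <- vector("list", n_games)
  for (g in seq_len(n_games)) {
    feats <- core
    for (j in seq_along(partial)) {
      # feature j is absent from exactly one game (games 4..7 by default)
      absent_game <- if (n_games >= 7L) 3L + j else (j %% n_games) + 1L
      if (g != absent_game) feats <- c(feats, partial[j])
    }
    if (n_games >= 7L && g <= 3L) feats <- c(feats, "gripVariance", "pauseCount")
    masks[[g]] <- feats
  }
  masks
}

#' Persistence-biased therapist difficulty policy
#'
#' Emulates how clinical staff set the three robot parameters from one
#' session to the next: most of the time the previous levels are kept; when
#' a level does change it moves one step harder if the patient's latent
#' performance exceeds the escalation threshold, one step easier otherwise,
#' clamped to the level set.
#'
#' @param prev_levels Named character vector with entries `stiffness`,
#'   `weight`, `viscosity`.
#' @param latent_performance Latent ability in `[0, 1]`.
#' @param config A [sim_config()].
#' @return Named character vector of the next levels.
#' @export
therapist_policy <- function(prev_levels, latent_performance, config) {
  sets <- robot_level_sets()
  out <- prev_levels
  for (param in names(sets)) {
    levs <- sets[[param]]
    check_levels(prev_levels[[param]], param)
    if (stats::runif(1) < config$therapist_persistence) next
    idx <- match(prev_levels[[param]], levs)
    step <- if (latent_performance > config$escalation_threshold) 1L else -1L
    out[[param]] <- levs[min(max(idx + step, 1L), length(levs))]
  }
  out
}

#' Simulate a synthetic rehabilitation cohort
#'
#' Generates per-round session logs, a patient table with demographics and
#' pre/post clinical scores, and the latent ground truth (per-day ability and
#' true recovery rate) used only by parameter-recovery tests. Each patient's
#' ability follows `a_t = min(1, a0 + rate * day)`; kinematic values are
#' game-specific baselines scaled by current ability with multiplicative
#' lognormal noise (guaranteeing non-negativity); discharge scores are the
#' scale maximum times ability at the last day, plus noise, clipped to the
#' scale and rounded.
#'
#' @param config A [sim_config()].
#' @return A list of class `rehab_cohort` with elements `rounds` (one row per
#'   game round), `patients` (one row per patient) and `latents` (list with
#'   `patients` and `ability` data frames).
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 3, seed = 7))
#' head(coh$rounds[, 1:8])
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  # uniform integer in [a, b]; safe when a == b (unlike sample(seq(a, b), 1))
  rint <- function(a, b) a + floor(stats::runif(1) * (b - a + 1L))

  feats <- config$all_features
  scale_max <- clinical_scale_max()
  # fixed per-(game, feature) baselines
  base <- matrix(stats::runif(config$n_games * length(feats), 0.5, 2),
                 nrow = config$n_games,
                 dimnames = list(NULL, feats))

  rounds_list <- vector("list", config$n_patients)
  patients_list <- vector("list", config$n_patients)
  lat_pat <- vector("list", config$n_patients)
  lat_abl <- vector("list", config$n_patients)

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    if (is.null(config$driver_feature)) {
      age <- round(stats::runif(1, 45, 85))
      gender <- stats::rbinom(1, 1, 0.5)
      latency <- round(stats::rlnorm(1, meanlog = 4, sdlog = 0.5))
    } else {
      # driver-isolation probe: demographics held constant so the injected
      # kinematic feature is the only patient-level cause of the outcome
      age <- 65
      gender <- 0
      latency <- 55
    }
    n_days <- if (stats::runif(1) < config$short_stay_prob)
      rint(3L, 9L)
    else
      rint(config$days_range[1], config$days_range[2])
    gaps <- sample(c(1L, 1L, 1L, 2L, 3L), n_days - 1L, replace = TRUE)
    offsets <- cumsum(c(0L, gaps))
    start_date <- as.Date("2024-01-08") + rint(0L, 180L)
    dates <- start_date + offsets

    a0 <- stats::runif(1, 0.2, 0.5)
    rate <- stats::runif(1, config$recovery_rate_range[1],
                         config$recovery_rate_range[2])
    ability <- pmin(1, a0 + rate * offsets)

    levels_now <- c(stiffness = "Low", weight = "Low", viscosity = "Low")
    day_rows <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      if (d > 1L)
        levels_now <- therapist_policy(levels_now, ability[d], config)
      n_rounds <- rint(config$rounds_per_day_range[1],
                       config$rounds_per_day_range[2])
      p_auto <- config$automode_prob_initial * config$automode_decay^(d - 1L)
      games <- sample(seq_len(config$n_games), n_rounds, replace = TRUE)
      auto <- stats::runif(n_rounds) < p_auto
      kin <- matrix(NA_real_, nrow = n_rounds, ncol = length(feats),
                    dimnames = list(NULL, feats))
      for (r in seq_len(n_rounds)) {
        mask <- config$game_feature_masks[[games[r]]]
        for (f in mask) {
          level <- if (auto[r]) {
            0.25  # passive rounds carry no active-motion signal
          } else if (!is.null(config$driver_feature) &&
                     f != config$driver_feature) {
            0.25 + 0.5
          } else {
            0.25 + ability[d]
          }
          val <- base[games[r], f] * level *
            exp(stats::rnorm(1, 0, config$noise_sd))
          if (stats::runif(1) < config$feature_missing_prob) val <- NA_real_
          kin[r, f] <- val
        }
      }
      day_rows[[d]] <- data.frame(
        patient_id = pid,
        date = format(dates[d]),
        game_id = games,
        automode = auto,
        stiffness = levels_now[["stiffness"]],
        weight = levels_now[["weight"]],
        viscosity = levels_now[["viscosity"]],
        kin,
        stringsAsFactors = FALSE
      )
    }
    rounds_list[[p]] <- do.call(rbind, day_rows)

    t0_true <- scale_max * ability[1]
    t1_true <- scale_max * ability[n_days]
    score_noise <- function(true, mx)
      round(pmin(mx, pmax(0, true + stats::rnorm(1, 0, config$noise_sd *
                                                   0.1 * mx))))
    t0 <- mapply(score_noise, t0_true, scale_max)
    t1 <- mapply(score_noise, t1_true, scale_max)
    if (stats::runif(1) < config$t1_missing_prob) t1[] <- NA_real_
    patients_list[[p]] <- data.frame(
      patient_id = pid, age = age, gender = gender, latency_days = latency,
      arat_t0 = t0[["arat"]], fma_t0 = t0[["fma"]], mi_t0 = t0[["mi"]],
      arat_t1 = t1[["arat"]], fma_t1 = t1[["fma"]], mi_t1 = t1[["mi"]],
      stringsAsFactors = FALSE
    )
    lat_pat[[p]] <- data.frame(
      patient_id = pid, a0 = a0, recovery_rate = rate,
      arat_t0_true = t0_true[["arat"]], fma_t0_true = t0_true[["fma"]],
      mi_t0_true = t0_true[["mi"]],
      arat_t1_true = t1_true[["arat"]], fma_t1_true = t1_true[["fma"]],
      mi_t1_true = t1_true[["mi"]],
      stringsAsFactors = FALSE
    )
    lat_abl[[p]] <- data.frame(patient_id = pid, date = format(dates),
                               ability = ability, stringsAsFactors = FALSE)
  }

  structure(
    list(
      rounds = do.call(rbind, rounds_list),
      patients = do.call(rbind, patients_list),
      latents = list(patients = do.call(rbind, lat_pat),
                     ability = do.call(rbind, lat_abl)),
      config = config
    ),
    class = "rehab_cohort"
  )
}

#' @export
print.rehab_cohort <- function(x, ...) {
  cat("Synthetic rehabilitation cohort: ", nrow(x$patients), " patients, ",
      nrow(x$rounds), " game rounds, ", x$config$n_games, " games\n", sep = "")
  invisible(x)
}

#' Write a cohort to CSV/JSON files
#'
#' Writes `rounds.csv` and `patients.csv` in the formats the ingest functions
#' read (empty cell = missing value) plus `latents.json` (test ground truth
#' only).
#'
#' @param cohort A `rehab_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(rounds = file.path(dir, "rounds.csv"),
             patients = file.path(dir, "patients.csv"),
             latents = file.path(dir, "latents.json"))
  utils::write.csv(cohort$rounds, paths[["rounds"]], row.names = FALSE,
                   na = "")
  utils::write.csv(cohort$patients, paths[["patients"]], row.names = FALSE,
                   na = "")
  jsonlite::write_json(cohort$latents, paths[["latents"]], digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

#' Read a cohort's round log and patient table from CSV
#'
#' @param rounds_path Path to `rounds.csv`.
#' @param patients_path Path to `patients.csv`.
#' @return List with `rounds` and `patients` data frames (empty cells become
#'   `NA`).
#' @export
read_cohort_csv <- function(rounds_path, patients_path) {
  rounds <- utils::read.csv(rounds_path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  rounds$automode <- as.logical(rounds$automode)
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                              na.strings = c("", "NA"))
  list(rounds = rounds, patients = patients)
}
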