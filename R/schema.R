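#' The 36-column per-time-step feature schema
#'
#' Every harmonized time-step of a patient series is described by 36 features
#' in five fixed groups: demographics (3), kinematic features (16), robot
#' difficulty parameters (3), one-hot game choice (7) and time-related
#' features (7). Column order is fixed and versioned; tensors carry this
#' schema as a sidecar so column meaning is always auditable.
#'
#' @param n_games Number of serious games available on the robot (default 7).
#' @return An object of class `feature_schema`: a list with the ordered
#'   column names per group and the full 36-name vector in `$columns`.
#' @examples
#' sch <- feature_schema()
#' length(sch$columns)  # 36
#' @export
feature_schema <- function(n_games = 7L) {
  n_games <- as.integer(n_games)
  if (is.na(n_games) || n_games < 2L)
    stop("n_games must be an integer >= 2", call. = FALSE)
  demographics <- c("age", "gender", "latency")
  kinematic <- kinematic_feature_names()
  robot <- c("stiffness", "weight", "viscosity")
  games <- paste0("game_", seq_len(n_games))
  time_related <- time_feature_names()
  columns <- c(demographics, kinematic, robot, games, time_related)
  structure(
    list(
      demographics = demographics,
      kinematic = kinematic,
      robot = robot,
      games = games,
      time_related = time_related,
      columns = columns,
      n_games = n_games,
      version = "1"
    ),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema v", x$version, ": ", length(x$columns), " columns (",
      length(x$demographics), " demographic + ", length(x$kinematic),
      " kinematic + ", length(x$robot), " robot + ", length(x$games),
      " game one-hot + ", length(x$time_related), " time-related)\n",
      sep = "")
  invisible(x)
}

#' Canonical kinematic feature names
#'
#' The 16 high-level kinematic features the robot derives from force and
#' position recordings of a serious-game round (speed, mechanical work
#' decompositions, precision, task distance, autonomy, energy and smoothness
#' summaries). Order is canonical for all downstream schemas.
#'
#' @return Character vector of length 16.
#' @export
kinematic_feature_names <- function() {
  c("userVelocityAvg", "workUserTotal", "workTanUserTotal", "precisionWork",
    "distanceTask", "autonomyDuration", "velocityNorm", "durationUser",
    "workTanRobot", "params", "workTanUserSelf", "overall", "calories",
    "timeUser", "smoothness_force", "smoothness_kin")
}

#' Names of the seven time-related features
#'
#' @return Character vector of length 7.
#' @export
time_feature_names <- function() {
  c("date_diff", "date_diff_session", "remaining_day_of_therapy",
    "number_of_sessions", "total_sessions_day", "total_sessions_incr",
    "automode_sessions")
}

#' One-hot encode the serious-game choice
#'
#' @param game_id Integer game identifier in `1..n_games`.
#' @param n_games Number of games (default 7).
#' @return Numeric indicator vector of length `n_games` with a single 1 at
#'   position `game_id`.
#' @examples
#' encode_game_choice(3)  # 0 0 1 0 0 0 0
#' @export
encode_game_choice <- function(game_id, n_games = 7L) {
  game_id <- as.integer(game_id)
  if (length(game_id) != 1L || is.na(game_id) ||
      game_id < 1L || game_id > n_games)
    stop("game_id must be a single integer in 1..", n_games, call. = FALSE)
  v <- numeric(n_games)
  v[game_id] <- 1
  v
}

# Level sets for the three robot difficulty parameters.
robot_level_sets <- function() {
  list(stiffness = c("Low", "Mid", "High"),
       weight = c("Low", "Mid", "High"),
       viscosity = c("Low", "High"))
}

# Validate a character vector of levels for one parameter; returns the input.
check_levels <- function(x, param) {
  levs <- robot_level_sets()[[param]]
  bad <- !(x %in% levs)
  if (any(bad))
    stop("invalid ", param, " level(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}

#' Clinical scale maxima
#'
#' Upper bounds of the three clinical scales used as prediction targets:
#' Action Research Arm Test (ARAT, 0-57), Fugl-Meyer Assessment upper
#' extremity (FMA, 0-66) and Motricity Index (MI, 0-100).
#'
#' @return Named numeric vector `c(arat = 57, fma = 66, mi = 100)`.
#' @export
clinical_scale_max <- function() {
  c(arat = 57, fma = 66, mi = 100)
}
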