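#' Build one normalized 36-element feature vector
#'
#' Concatenates the already-normalized components of one session in schema
#' order: demographics | kinematics | robot parameters | one-hot game |
#' time-related. Demographics repeat identically at every time-step of a
#' patient.
#'
#' @param demographics Numeric vector of 3 normalized demographic values.
#' @param kinematics Named numeric vector of the 16 normalized kinematic
#'   values.
#' @param robot Numeric vector of 3 normalized robot parameter values.
#' @param game_id Game identifier (one-hot encoded internally).
#' @param time_features Named numeric vector of the 7 normalized
#'   time-related values.
#' @param schema A [feature_schema()].
#' @return Numeric vector of length 36, named by schema columns.
#' @export
build_feature_vector <- function(demographics, kinematics, robot, game_id,
                                 time_features, schema = feature_schema()) {
  v <- c(as.numeric(demographics),
         as.numeric(kinematics[schema$kinematic]),
         as.numeric(robot),
         encode_game_choice(game_id, schema$n_games),
         as.numeric(time_features[schema$time_related]))
  if (length(v) != length(schema$columns))
    stop("feature vector width ", length(v), " != schema width ",
         length(schema$columns), call. = FALSE)
  names(v) <- schema$columns
  v
}

# Normalized m x 36 matrix for one patient's final series.
build_patient_matrix <- function(series, record, state,
                                 schema = feature_schema()) {
  series <- normalize_kinematics(series, state)
  tf <- normalize_time_features(series)
  series <- tf$series
  demo <- normalize_demographics(record, state)
  m <- nrow(series)
  out <- matrix(0, nrow = m, ncol = length(schema$columns),
                dimnames = list(NULL, schema$columns))
  rp <- normalize_robot_params(list(stiffness = series$stiffness,
                                    weight = series$weight,
                                    viscosity = series$viscosity))
  for (i in seq_len(m)) {
    out[i, ] <- build_feature_vector(
      demo,
      unlist(series[i, schema$kinematic, drop = FALSE]),
      c(rp$stiffness[i], rp$weight[i], rp$viscosity[i]),
      series$game_id[i],
      unlist(series[i, schema$time_related, drop = FALSE]),
      schema
    )
  }
  out
}

#' Assemble the cohort tensor
#'
#' Stacks every patient's normalized, harmonized series into the
#' model-facing arrays: `values` (patients x 64 x 36), `mask` (patients x
#' 64, 1 = real time-step) and `labels` (patients x 3 normalized discharge
#' scores, the ground truth of the outcome model).
#'
#' @param prepared A prepared cohort from [prepare_cohort()] (final sessions
#'   with time features, retained patients).
#' @param state A fitted `normalization_state`.
#' @param patient_ids Patients to include, in order (default: all retained).
#' @param target Series length (default 64).
#' @param schema A [feature_schema()].
#' @return Object of class `cohort_tensor` with `values`, `mask`, `labels`,
#'   `patient_ids` and the `schema`.
#' @export
assemble_cohort_tensor <- function(prepared, state, patient_ids = NULL,
                                   target = 64L,
                                   schema = feature_schema()) {
  if (is.null(patient_ids)) patient_ids <- prepared$patients$patient_id
  p <- length(patient_ids)
  values <- array(0, dim = c(p, target, length(schema$columns)),
                  dimnames = list(patient_ids, NULL, schema$columns))
  mask <- matrix(0L, nrow = p, ncol = target,
                 dimnames = list(patient_ids, NULL))
  labels <- matrix(NA_real_, nrow = p, ncol = 3,
                   dimnames = list(patient_ids, c("arat", "fma", "mi")))
  for (i in seq_len(p)) {
    pid <- patient_ids[i]
    series <- prepared$sessions[prepared$sessions$patient_id == pid, ,
                                drop = FALSE]
    record <- prepared$patients[prepared$patients$patient_id == pid, ,
                                drop = FALSE]
    if (nrow(record) != 1L)
      stop("patient ", pid, " not found in prepared cohort", call. = FALSE)
    mat <- build_patient_matrix(series, record, state, schema)
    padded <- pad_series(mat, target)
    values[i, , ] <- padded$values
    mask[i, ] <- padded$mask
    labels[i, ] <- normalize_clinical_scores(
      list(arat = record$arat_t1, fma = record$fma_t1, mi = record$mi_t1))
  }
  structure(list(values = values, mask = mask, labels = labels,
                 patient_ids = patient_ids, schema = schema),
            class = "cohort_tensor")
}

#' @export
print.cohort_tensor <- function(x, ...) {
  cat("Cohort tensor: ", dim(x$values)[1], " patients x ", dim(x$values)[2],
      " time-points x ", dim(x$values)[3], " features (",
      sum(x$mask), " real time-steps)\n", sep = "")
  invisible(x)
}

#' Build lookback windows for the difficulty recommender
#'
#' Slides a window of `lookback` consecutive valid time-steps over each
#' patient's series; the label is the robot-parameter class triple of the
#' session immediately after the window. A patient with `m` valid steps
#' yields `max(0, m - lookback)` windows; windows never span padded rows and
#' labels never come from padded rows.
#'
#' @param tensor A `cohort_tensor`.
#' @param lookback Number of previous time-points per window.
#' @return Object of class `lookback_dataset` with `x` (windows x lookback x
#'   36), `labels` (data frame of 1-based class indices for stiffness,
#'   weight, viscosity) and `provenance` (patient id, window end index).
#' @export
build_lookback_windows <- function(tensor, lookback) {
  lookback <- as.integer(lookback)
  if (is.na(lookback) || lookback < 1L)
    stop("lookback must be >= 1", call. = FALSE)
  sch <- tensor$schema
  n_feat <- length(sch$columns)
  xs <- list(); st <- list(); we <- list(); vi <- list(); pids <- list()
  ends <- list()
  for (i in seq_along(tensor$patient_ids)) {
    m <- sum(tensor$mask[i, ])
    if (m <= lookback) next
    for (e in lookback:(m - 1L)) {
      xs[[length(xs) + 1L]] <-
        tensor$values[i, (e - lookback + 1L):e, , drop = FALSE]
      nxt <- tensor$values[i, e + 1L, ]
      st[[length(st) + 1L]] <- invert_robot_params(nxt[["stiffness"]],
                                                   "stiffness")
      we[[length(we) + 1L]] <- invert_robot_params(nxt[["weight"]], "weight")
      vi[[length(vi) + 1L]] <- invert_robot_params(nxt[["viscosity"]],
                                                   "viscosity")
      pids[[length(pids) + 1L]] <- tensor$patient_ids[i]
      ends[[length(ends) + 1L]] <- e
    }
  }
  n <- length(xs)
  if (n == 0L) {
    warning("no patient has more than ", lookback,
            " valid time-steps; empty window set", call. = FALSE)
    x <- array(0, dim = c(0L, lookback, n_feat))
  } else {
    x <- array(0, dim = c(n, lookback, n_feat),
               dimnames = list(NULL, NULL, sch$columns))
    for (j in seq_len(n)) x[j, , ] <- xs[[j]]
  }
  structure(list(
    x = x,
    labels = data.frame(stiffness = as.integer(unlist(st)),
                        weight = as.integer(unlist(we)),
                        viscosity = as.integer(unlist(vi))),
    provenance = data.frame(patient_id = as.character(unlist(pids)),
                            end = as.integer(unlist(ends))),
    lookback = lookback, schema = sch
  ), class = "lookback_dataset")
}

#' @export
print.lookback_dataset <- function(x, ...) {
  cat("Lookback dataset: ", dim(x$x)[1], " windows x ", x$lookback,
      " time-points x ", dim(x$x)[3], " features\n", sep = "")
  invisible(x)
}
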