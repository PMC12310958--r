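toy_state <- function() {
  sessions <- toy_sessions(dates = c(0, 1), games = c(1, 2),
                           extra = list(userVelocityAvg = c(0.8, 0.4)))
  patients <- data.frame(patient_id = "P1", age = 80, gender = 1,
                         latency_days = 89)
  fit_normalizer(sessions, patients, "userVelocityAvg")
}

test_that("latency normalizes on the log1p scale", {
  sessions <- toy_sessions(dates = 0, games = 1,
                           extra = list(userVelocityAvg = 1))
  patients <- data.frame(patient_id = c("P1", "P2"), age = c(60, 80),
                         gender = c(0, 1), latency_days = c(29, 89))
  st <- fit_normalizer(sessions, patients, "userVelocityAvg")
  d1 <- normalize_demographics(patients[1, ], st)
  d2 <- normalize_demographics(patients[2, ], st)
  expect_equal(unname(d1[["latency"]]), log1p(29) / log1p(89),
               tolerance = 1e-12)
  expect_equal(unname(d2[["latency"]]), 1.0)
  expect_equal(round(d1[["latency"]], 3), 0.756)
  expect_equal(unname(d2[["age"]]), 1.0)   # cohort age maximum
  d0 <- normalize_demographics(
    data.frame(age = 60, gender = 0, latency_days = 0), st)
  expect_equal(unname(d0[["latency"]]), 0.0)
})

test_that("kinematics scale by their per-game training maximum and clip", {
  sessions <- rbind(
    toy_sessions(dates = c(0, 1), games = c(2, 2),
                 extra = list(userVelocityAvg = c(0.8, 0.4))),
    toy_sessions("P2", dates = 0, games = 1,
                 extra = list(userVelocityAvg = 2)))
  patients <- data.frame(patient_id = c("P1", "P2"), age = c(60, 61),
                         gender = 0, latency_days = 10)
  st <- fit_normalizer(sessions, patients, "userVelocityAvg")
  expect_equal(unname(st$kin_max[2, "userVelocityAvg"]), 0.8)
  expect_equal(unname(st$kin_max[1, "userVelocityAvg"]), 2)
  out <- normalize_kinematics(sessions, st)
  expect_equal(out$userVelocityAvg, c(1.0, 0.5, 1.0))
  # unseen larger value at test time clips to 1
  test_s <- toy_sessions(dates = 0, games = 2,
                         extra = list(userVelocityAvg = 0.96))
  expect_equal(normalize_kinematics(test_s, st)$userVelocityAvg, 1.0)
})

test_that("refitting on the same cohort reproduces the state", {
  expect_equal(toy_state(), toy_state())
})

test_that("robot levels map onto the ordinal grid", {
  v <- normalize_robot_params(list(stiffness = "High", weight = "Low",
                                   viscosity = "High"))
  expect_equal(unname(v), c(1, 1 / 3, 1))
  v <- normalize_robot_params(list(stiffness = "Low", weight = "Low",
                                   viscosity = "Low"))
  expect_equal(unname(v), c(1 / 3, 1 / 3, 1 / 2))
  v <- normalize_robot_params(list(stiffness = "Mid", weight = "High",
                                   viscosity = "Low"))
  expect_equal(v[["stiffness"]], 2 / 3)
  expect_error(normalize_robot_params(list(stiffness = "VeryHigh",
                                           weight = "Low",
                                           viscosity = "Low")),
               "stiffness")
})

test_that("normalized robot values invert to exact class indices", {
  for (lv in c("Low", "Mid", "High")) {
    v <- normalize_robot_params(list(stiffness = lv, weight = lv,
                                     viscosity = if (lv == "Mid") "Low"
                                                 else lv))
    expect_identical(invert_robot_params(v[["stiffness"]], "stiffness",
                                         as_level = TRUE), lv)
  }
  expect_identical(invert_robot_params(c(1 / 2, 1), "viscosity",
                                       as_level = TRUE), c("Low", "High"))
  expect_error(invert_robot_params(0.1, "stiffness"), "grid")
})

test_that("time features normalize per patient to a unit maximum", {
  s <- toy_sessions(dates = c(0, 2, 7), games = 1)
  s <- compute_time_features(s, NULL)
  out <- normalize_time_features(s)
  expect_equal(out$series$date_diff, c(0, 2 / 7, 1))
  expect_equal(max(out$series$total_sessions_incr), 1)
  expect_equal(out$series$automode_sessions, c(0, 0, 0))  # all-zero stays 0
})

test_that("every nonzero time feature attains 1 after normalization", {
  prep <- small_prepared()
  for (pid in prep$patients$patient_id[1:5]) {
    sub <- prep$sessions[prep$sessions$patient_id == pid, ]
    out <- normalize_time_features(sub)$series
    for (f in time_feature_names()) {
      v <- out[[f]]
      expect_true(all(v >= 0 & v <= 1))
      if (any(v > 0)) expect_equal(max(v), 1)
    }
  }
})

test_that("clinical score normalization is exact and invertible", {
  expect_equal(unname(normalize_clinical_scores(
    list(arat = 57, fma = 33, mi = 50))), c(1, 0.5, 0.5))
  v <- normalize_clinical_scores(list(arat = 12, fma = 41, mi = 42))
  back <- denormalize_clinical_scores(v)
  expect_equal(unname(back[["mi"]]), 42, tolerance = 1e-12)
  expect_equal(unname(back), c(12, 41, 42), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:25) {
    s <- list(arat = runif(1, 0, 57), fma = runif(1, 0, 66),
              mi = runif(1, 0, 100))
    expect_equal(unname(denormalize_clinical_scores(
      normalize_clinical_scores(s))), unlist(s, use.names = FALSE),
      tolerance = 1e-12)
  }
  expect_error(normalize_clinical_scores(list(arat = 58, fma = 0, mi = 0)),
               "out of bounds")
})

test_that("all assembled training features lie in [0, 1]", {
  tens <- small_tensor()
  expect_true(all(tens$values >= 0 & tens$values <= 1))
  expect_true(all(tens$labels >= 0 & tens$labels <= 1))
})
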