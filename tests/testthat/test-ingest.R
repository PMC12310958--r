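make_rounds <- function(pid, dates, games, automode = FALSE, value = 1,
                        stiffness = "Mid", weight = "Mid",
                        viscosity = "Low") {
  data.frame(
    patient_id = pid,
    date = format(as.Date("2024-03-04") + dates),
    game_id = games,
    automode = automode,
    stiffness = stiffness, weight = weight, viscosity = viscosity,
    userVelocityAvg = value,
    stringsAsFactors = FALSE
  )
}

test_that("automode rounds are removed but counted per patient-day", {
  rounds <- make_rounds("P1", c(0, 0, 0, 0, 0), c(1, 1, 2, 3, 3),
                        automode = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  out <- exclude_automode_rounds(rounds)
  expect_equal(nrow(out$rounds), 3)
  expect_false(any(out$rounds$automode))
  expect_equal(out$automode_counts$n_automode, 2L)
  # conservation: every input round is active or counted
  expect_equal(nrow(out$rounds) + sum(out$automode_counts$n_automode),
               nrow(rounds))
})

test_that("a patient with only automode rounds yields an empty series", {
  rounds <- make_rounds("P9", c(0, 1), c(1, 1), automode = TRUE)
  out <- exclude_automode_rounds(rounds)
  expect_equal(nrow(out$rounds), 0)
  expect_equal(sum(out$automode_counts$n_automode), 2L)
})

test_that("without automode the input passes through with zero counts", {
  rounds <- make_rounds("P1", c(0, 1), c(1, 2))
  out <- exclude_automode_rounds(rounds)
  expect_equal(out$rounds$game_id, rounds$game_id)
  expect_true(all(out$automode_counts$n_automode == 0))
})

test_that("same-day rounds of one game average into a single session", {
  rounds <- make_rounds("P1", c(0, 0), c(3, 3), value = c(0.2, 0.4))
  s <- average_rounds_to_sessions(rounds)
  expect_equal(nrow(s), 1)
  expect_equal(s$userVelocityAvg, 0.3)
  expect_equal(s$n_rounds, 2L)
})

test_that("a single round maps to an identical session", {
  rounds <- make_rounds("P1", 0, 5, value = 0.7)
  s <- average_rounds_to_sessions(rounds)
  expect_equal(s$userVelocityAvg, 0.7)
  expect_equal(s$game_id, 5)
  expect_equal(s$n_rounds, 1L)
})

test_that("different games on one day become distinct same-date time-steps", {
  rounds <- make_rounds("P1", c(0, 0), c(1, 2), value = c(0.1, 0.9))
  s <- average_rounds_to_sessions(rounds)
  expect_equal(nrow(s), 2)
  expect_equal(length(unique(s$date)), 1)
  expect_setequal(s$game_id, c(1, 2))
})

test_that("averaging already-averaged sessions is the identity", {
  rounds <- make_rounds("P1", c(0, 0, 1), c(1, 2, 1),
                        value = c(0.1, 0.9, 0.5))
  s1 <- average_rounds_to_sessions(rounds)
  s1$automode <- FALSE
  s2 <- average_rounds_to_sessions(s1[, names(s1) != "n_rounds"])
  expect_equal(s2$userVelocityAvg, s1$userVelocityAvg)
  expect_equal(s2$date, s1$date)
  expect_equal(s2$game_id, s1$game_id)
})

test_that("mutuality filter keeps features strictly above the threshold", {
  kin <- kinematic_feature_names()
  masks6 <- lapply(1:7, function(g) if (g == 7) setdiff(kin, "overall")
                   else kin)
  expect_true("overall" %in% filter_features_by_mutuality(NULL, masks6))
  masks4 <- lapply(1:7, function(g) if (g <= 4) kin
                   else setdiff(kin, "overall"))
  expect_false("overall" %in% filter_features_by_mutuality(NULL, masks4))
  masks_all <- lapply(1:7, function(g) kin)
  expect_identical(filter_features_by_mutuality(NULL, masks_all), kin)
  # exactly at the threshold the feature is dropped (strict >)
  masks_thr <- lapply(1:10, function(g) if (g <= 7) kin
                      else setdiff(kin, "overall"))
  expect_false("overall" %in% filter_features_by_mutuality(NULL, masks_thr))
  expect_error(filter_features_by_mutuality(data.frame(), masks_all),
               "empty")
})

test_that("mutuality agrees with a brute-force membership count", {
  set.seed(42)
  kin <- kinematic_feature_names()
  for (rep in 1:20) {
    masks <- lapply(1:7, function(g) sample(kin, sample(8:16, 1)))
    retained <- filter_features_by_mutuality(NULL, masks)
    for (f in kin) {
      expect_identical(f %in% retained, oracle_mutuality(masks, f) > 0.70,
                       info = paste("rep", rep, f))
    }
  }
})

test_that("missing values fill from the same date first", {
  s <- toy_sessions(dates = c(0, 0, 0), games = 1:3,
                    extra = list(userVelocityAvg = c(0.2, NA, 0.4)))
  out <- fill_missing_values(s, "userVelocityAvg")
  expect_equal(out$userVelocityAvg, c(0.2, 0.3, 0.4))
})

test_that("a day with no observed value front-fills from the prior day", {
  s <- toy_sessions(dates = c(0, 1), games = c(1, 1),
                    extra = list(userVelocityAvg = c(0.5, NA)))
  out <- fill_missing_values(s, "userVelocityAvg")
  expect_equal(out$userVelocityAvg, c(0.5, 0.5))
})

test_that("fill is the identity when nothing is missing, back-fills at the
           start, and zero-fills a never-observed feature with a warning", {
  s <- toy_sessions(dates = 0:2, games = c(1, 2, 3),
                    extra = list(userVelocityAvg = c(0.1, 0.2, 0.3),
                                 overall = c(NA, 0.6, NA),
                                 calories = NA_real_))
  expect_warning(out <- fill_missing_values(s, c("userVelocityAvg",
                                                 "overall", "calories")),
                 "never observed")
  expect_equal(out$userVelocityAvg, c(0.1, 0.2, 0.3))
  expect_equal(out$overall, c(0.6, 0.6, 0.6))  # back-fill then front-fill
  expect_equal(out$calories, c(0, 0, 0))
})

test_that("patient exclusions apply both criteria with the stated precedence", {
  pats <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    age = 60, gender = 1, latency_days = 30,
    arat_t0 = 10, fma_t0 = 10, mi_t0 = 10,
    arat_t1 = c(20, NA, 20, NA), fma_t1 = c(20, 20, 20, NA),
    mi_t1 = c(20, 20, 20, NA),
    stringsAsFactors = FALSE
  )
  sessions <- rbind(
    toy_sessions("A", dates = 0:9, games = 1),    # 10 dates, T1 present
    toy_sessions("B", dates = 0:11, games = 1),   # 12 dates, T1 missing
    toy_sessions("C", dates = 0:8, games = 1),    # 9 dates
    toy_sessions("D", dates = 0:3, games = 1)     # fails both
  )
  out <- apply_patient_exclusions(pats, sessions, min_attendances = 10)
  expect_identical(out$patients$patient_id, "A")   # 10 is inclusive
  r <- out$report
  expect_equal(r$n_input_patients, 4)
  expect_equal(r$n_retained, 1)
  expect_equal(r$n_excluded_no_post_assessment, 2)  # B and D (precedence)
  expect_equal(r$n_excluded_too_few_attendances, 1)
  expect_equal(r$n_retained + r$n_excluded_no_post_assessment +
                 r$n_excluded_too_few_attendances, r$n_input_patients)
  expect_identical(
    r$reasons$reason[r$reasons$patient_id == "D"], "no_post_assessment")
  expect_false("B" %in% out$sessions$patient_id)
})
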