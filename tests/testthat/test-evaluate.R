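test_that("error metrics match hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(mae(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 4)), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 4)), 2 / 3, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "equal length")
  expect_error(mae(numeric(0), numeric(0)), "at least one")
})

test_that("regression and classification metrics agree with brute force on
           1000 random vectors", {
  set.seed(2024)
  for (rep in 1:1000) {
    n <- sample(2:12, 1)
    y <- runif(n)
    yh <- runif(n)
    expect_equal(rmse(y, yh), oracle_rmse(y, yh), tolerance = 1e-12)
    expect_equal(mae(y, yh), oracle_mae(y, yh), tolerance = 1e-12)
    k <- sample(2:3, 1)
    yc <- sample(1:k, n, replace = TRUE)
    yhc <- sample(1:k, n, replace = TRUE)
    expect_equal(overall_accuracy(yc, yhc), oracle_oa(yc, yhc),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(f1_score(yc, yhc, k)),
                 oracle_f1_weighted(yc, yhc, k), tolerance = 1e-12)
    mx <- runif(1, 1, 100)
    expect_equal(percentage_difference(y[1] * mx, yh[1] * mx, mx)$pd,
                 (y[1] * mx - yh[1] * mx) / mx, tolerance = 1e-12)
  }
})

test_that("overall accuracy follows the confusion-count definition", {
  # TP=3, TN=5, FP=1, FN=1 in a binary problem (positive class = 2)
  y <- c(rep(2, 4), rep(1, 6))
  yh <- c(rep(2, 3), 1, rep(1, 5), 2)
  expect_equal(overall_accuracy(y, yh), 0.8)
})

test_that("F1 is the harmonic mean of precision and recall", {
  # both precision and recall 0.75 for the positive class
  y <- c(2, 2, 2, 2, 1, 1, 1, 1)
  yh <- c(2, 2, 2, 1, 2, 1, 1, 1)
  k <- 2
  tp <- sum(y == 2 & yh == 2); fp <- sum(y != 2 & yh == 2)
  fn <- sum(y == 2 & yh != 2)
  expect_equal(tp / (tp + fp), 0.75)
  expect_equal(tp / (tp + fn), 0.75)
  f1_pos <- 2 * 0.75 * 0.75 / (0.75 + 0.75)
  expect_equal(f1_pos, 0.75)
  expect_equal(oracle_f1_weighted(y, yh, k),
               suppressWarnings(f1_score(y, yh, k)))
  expect_equal(f1_score(1:3, 1:3), 1)
  expect_equal(overall_accuracy(1:3, 1:3), 1)
})

test_that("undefined per-class precision or recall yields a warned zero", {
  y <- c(1, 1, 2, 2)
  yh <- c(1, 1, 1, 1)  # class 2 never predicted
  expect_warning(f1 <- f1_score(y, yh, 2), "undefined")
  expect_lt(f1, 1)
})

test_that("percentage difference carries the stated sign convention", {
  r <- percentage_difference(57, 45.6, 57)
  expect_equal(r$pd, 0.2, tolerance = 1e-12)      # under-prediction
  expect_equal(percentage_difference(40, 40, 57)$pd, 0)
  expect_equal(percentage_difference(40, 50, 100)$pd, -0.1,
               tolerance = 1e-12)                  # over-prediction
  expect_error(percentage_difference(1, 1, 0), "max_score")
})

test_that("MCID groups split at +/-10% with inclusive boundaries", {
  expect_identical(assign_mcid_group(-0.10), "within")
  expect_identical(assign_mcid_group(0.10), "within")
  expect_identical(assign_mcid_group(0), "within")
  expect_identical(assign_mcid_group(0.25), "under_predicted")
  expect_identical(assign_mcid_group(-0.2), "over_predicted")
  expect_identical(assign_mcid_group(c(-0.5, 0.0, 0.5)),
                   c("over_predicted", "within", "under_predicted"))
  expect_error(assign_mcid_group(NaN), "finite")
})

test_that("each evaluated patient lands in exactly one MCID group per scale", {
  pds <- runif(50, -0.5, 0.5)
  g <- assign_mcid_group(pds)
  expect_true(all(g %in% c("within", "over_predicted", "under_predicted")))
  expect_length(g, 50)
})

test_that("session-error pooling matches a brute-force three-patient toy", {
  preds <- list(
    A = matrix(c(0.5, 0.6, 0.5, 0.6, 0.5, 0.6), ncol = 3),
    B = matrix(0.2, nrow = 1, ncol = 3),
    C = matrix(c(0.9, 0.8, 0.7, 0.9, 0.8, 0.7, 0.9, 0.8, 0.7), ncol = 3)
  )
  labels <- matrix(c(0.5, 0.4, 0.6,
                     0.5, 0.4, 0.6,
                     0.5, 0.4, 0.6), ncol = 3,
                   dimnames = list(c("A", "B", "C"), c("arat", "fma", "mi")))
  folds <- list(f1 = c("A", "B"), f2 = "C")
  agg <- aggregate_session_errors(preds, labels, folds)
  # labels fill column-major: A = 0.5, B = 0.4, C = 0.6 on every scale;
  # brute force, pooled over steps within fold f1, scale arat
  errs <- c(0.5 - 0.5, 0.6 - 0.5, 0.2 - 0.4)
  expect_equal(agg$rmse[agg$fold == "f1" & agg$scale == "arat"],
               sqrt(mean(errs^2)), tolerance = 1e-12)
  expect_equal(agg$mae[agg$fold == "f1" & agg$scale == "arat"],
               mean(abs(errs)), tolerance = 1e-12)
  # pooling differs from averaging per-patient means (weighting by steps)
  per_patient <- mean(c(mean(abs(c(0, 0.1))), 0.2))
  expect_false(isTRUE(all.equal(
    agg$mae[agg$fold == "f1" & agg$scale == "arat"], per_patient)))
  pm <- attr(agg, "patient_mean")
  expect_equal(unname(pm["A", 1]), 0.55)
  expect_error(aggregate_session_errors(preds, labels, list(bad = "ZZZ")),
               "no evaluated patients")
})

test_that("constant predictions give zero fold error", {
  preds <- list(A = matrix(0.5, nrow = 4, ncol = 3))
  labels <- matrix(0.5, 1, 3, dimnames = list("A", c("arat", "fma", "mi")))
  agg <- aggregate_session_errors(preds, labels, list(f = "A"))
  expect_true(all(agg$rmse == 0))
  expect_true(all(agg$mae == 0))
})

test_that("paired fold comparison has the exact signed-rank null", {
  expect_warning(res <- compare_models(rep(0.5, 6), rep(0.5, 6)), "tied")
  expect_equal(res$p_value, 1)
  a <- c(0.50, 0.52, 0.48, 0.47, 0.55, 0.51, 0.49, 0.53, 0.50, 0.52)
  b <- a + seq(0.01, 0.10, length.out = 10)  # strictly dominated, no ties
  res <- compare_models(a, b)
  expect_equal(res$p_value, 2 / 2^10, tolerance = 1e-12)
  flipped <- compare_models(b, a)
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(flipped$mean_diff, -res$mean_diff)
  expect_error(compare_models(1:3, 1:4), "paired")
})

test_that("permutation importance is normalized and nulls out ignored
           features", {
  tens <- small_tensor()
  # the cohort-mean predictor ignores every feature
  base <- cohort_mean_predictor(tens)
  imp <- permutation_importance(base, tens, n_repeats = 2, seed = 1)
  expect_true(all(attr(imp, "raw") == 0))
  expect_true(all(unclass(imp) == 0))
  # a quick recurrent fit: importances normalize to one
  fit <- outcome_lstm(tens, outcome_model_config(
    optimizer = "adam", learning_rate = 1e-3, fallback_lr = 1e-3,
    max_epochs = 4, patience = 4, min_epochs = 1, n_restarts = 1))
  imp2 <- permutation_importance(fit, tens, n_repeats = 2, seed = 1)
  expect_equal(sum(imp2), 1, tolerance = 1e-9)
  expect_length(imp2, 36)
  expect_named(top_features(imp2, 5))
  expect_length(top_features(imp2, 5), 5)
})

test_that("fold metrics summarize into the mean/sd/min/max table", {
  m <- data.frame(model = rep(c("a", "b"), each = 4),
                  scale = "fma",
                  fold = rep(paste0("f", 1:4), 2),
                  rmse = c(1, 2, 3, 4, 2, 2, 2, 2),
                  mae = c(1, 1, 1, 1, 3, 3, 3, 3))
  s <- summarize_eval_metrics(m, c("model", "scale"), c("rmse", "mae"))
  a_rmse <- s[s$group == "a / fma" & s$metric == "rmse", ]
  expect_equal(a_rmse$mean, 2.5)
  expect_equal(a_rmse$sd, sd(1:4))
  expect_equal(a_rmse$min, 1)
  expect_equal(a_rmse$max, 4)
})
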