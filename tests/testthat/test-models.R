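fast_cfg <- function(...) {
  args <- utils::modifyList(
    list(optimizer = "adam", learning_rate = 1e-3, fallback_lr = 1e-3,
         max_epochs = 4L, patience = 4L, min_epochs = 1L, n_restarts = 1L),
    list(...))
  do.call(outcome_model_config, args)
}

test_that("the outcome model emits finite per-step predictions in [0, 1]", {
  tens <- small_tensor()
  fit <- outcome_lstm(tens, fast_cfg())
  preds <- predict(fit, tens)
  expect_length(preds, length(tens$patient_ids))
  for (i in c(1, length(preds))) {
    p <- preds[[i]]
    expect_equal(ncol(p), 3)
    expect_equal(nrow(p), sum(tens$mask[i, ]))
    expect_true(all(is.finite(p)))
    expect_true(all(p >= 0 & p <= 1))
  }
  dn <- predict(fit, tens, denormalize = TRUE)
  mx <- clinical_scale_max()
  expect_true(all(dn[[1]][, "arat"] <= mx[["arat"]]))
  expect_true(all(dn[[1]][, "mi"] <= mx[["mi"]]))
})

test_that("padded rows never influence predictions, loss or metrics", {
  tens <- small_tensor()
  fit <- outcome_lstm(tens, fast_cfg())
  p0 <- predict(fit, tens)
  perturbed <- tens
  for (i in seq_along(tens$patient_ids)) {
    m <- sum(tens$mask[i, ])
    if (m < 64)
      perturbed$values[i, (m + 1):64, ] <- runif((64 - m) * 36)
  }
  p1 <- predict(fit, perturbed)
  expect_identical(p0, p1)
  folds <- list(all = tens$patient_ids)
  a0 <- aggregate_session_errors(p0, tens$labels, folds)
  a1 <- aggregate_session_errors(p1, perturbed$labels, folds)
  expect_identical(a0$rmse, a1$rmse)
  # training on perturbed padding gives the identical model
  f2 <- outcome_lstm(perturbed, fast_cfg())
  expect_identical(fit$weights, f2$weights)
})

test_that("training is deterministic given a seed, and frozen at rate 0", {
  tens <- small_tensor()
  a <- outcome_lstm(tens, fast_cfg(seed = 5L))
  b <- outcome_lstm(tens, fast_cfg(seed = 5L))
  expect_identical(a$weights, b$weights)
  expect_identical(a$history, b$history)
  c1 <- outcome_lstm(tens, fast_cfg(seed = 5L, learning_rate = 0,
                                    fallback_lr = 0, max_epochs = 1L))
  c3 <- outcome_lstm(tens, fast_cfg(seed = 5L, learning_rate = 0,
                                    fallback_lr = 0, max_epochs = 3L))
  expect_identical(c1$weights, c3$weights)  # zero rate -> no updates
})

test_that("architecture size is reproducible and matches the layer spec", {
  tens <- small_tensor()
  a <- outcome_lstm(tens, fast_cfg(max_epochs = 1L))
  b <- outcome_lstm(tens, fast_cfg(max_epochs = 1L, seed = 99L))
  expect_equal(n_parameters(a), n_parameters(b))
  # 6 layers: first 4*32*(36+32+1), rest 4*32*(32+32+1); head 32*3+3
  expected <- 4 * 32 * (36 + 32 + 1) + 5 * 4 * 32 * (32 + 32 + 1) +
    (32 * 3 + 3)
  expect_equal(n_parameters(a), expected)
})

test_that("difficulty recommenders emit proper probabilities and argmax", {
  tens <- small_tensor()
  w <- build_lookback_windows(tens, 3)
  cfg <- difficulty_model_config("weight", max_epochs = 5, min_epochs = 1)
  fit <- difficulty_lstm(w, cfg)
  out <- predict(fit, w)
  expect_true(all(abs(rowSums(out$prob) - 1) < 1e-6))
  expect_identical(colnames(out$prob), c("Low", "Mid", "High"))
  expect_identical(out$level, c("Low", "Mid", "High")[out$class])
  expect_identical(unname(apply(out$prob, 1, which.max)), out$class)
  # single-window matrix interface and length validation
  one <- predict(fit, w$x[1, , ])
  expect_equal(nrow(one$prob), 1)
  expect_error(predict(fit, w$x[1, 1:2, ]), "lookback")
  expect_error(difficulty_lstm(w, difficulty_model_config("viscosity")),
               "lookback")
})

test_that("recommend_parameters applies each model's own lookback", {
  tens <- small_tensor()
  models <- list(
    stiffness = difficulty_lstm(build_lookback_windows(tens, 3),
                                difficulty_model_config("stiffness",
                                                        max_epochs = 3,
                                                        min_epochs = 1)),
    viscosity = difficulty_lstm(build_lookback_windows(tens, 5),
                                difficulty_model_config("viscosity",
                                                        max_epochs = 3,
                                                        min_epochs = 1)))
  recent <- rehabdst:::prefix_matrix(tens, 1)
  rec <- recommend_parameters(models, recent)
  expect_named(rec, c("stiffness", "viscosity"))
  expect_true(rec$stiffness$level %in% c("Low", "Mid", "High"))
  expect_true(rec$viscosity$level %in% c("Low", "High"))
  expect_error(recommend_parameters(models, recent[1:2, , drop = FALSE]),
               "at least")
})

test_that("cross-validation folds partition patients deterministically", {
  ids60 <- sprintf("P%03d", 1:60)
  f <- make_cv_folds(ids60, k = 5, seed = 42)
  expect_equal(unname(lengths(f$folds)), rep(12L, 5))
  ids78 <- sprintf("P%03d", 1:78)
  f78 <- make_cv_folds(ids78, k = 5, seed = 42)
  expect_equal(sort(unname(lengths(f78$folds)), decreasing = TRUE),
               c(16L, 16L, 16L, 15L, 15L))
  expect_identical(sort(unlist(f78$folds, use.names = FALSE)), ids78)
  f2 <- make_cv_folds(ids78, k = 5, seed = 42)
  expect_identical(f78, f2)
  expect_error(make_cv_folds(ids60, k = 1), ">= 2")
  expect_error(make_cv_folds(ids60[1:3], k = 5), "exceeds")
})

test_that("random-forest baselines honor the stated hyperparameters", {
  oc <- rf_config("outcome")
  expect_equal(oc$num_trees, 300L)
  expect_equal(oc$max_depth, 10L)
  expect_equal(oc$min_samples_split, 5L)
  expect_equal(oc$min_samples_leaf, 20L)
  rc <- rf_config("recommendation")
  expect_equal(unlist(rc[1:4], use.names = FALSE), c(350L, 15L, 5L, 5L))

  tens <- small_tensor()
  rf <- fit_rf_outcome(tens, oc, seed = 1)
  expect_equal(rf$fits$arat$num.trees, 300)
  p1 <- predict(rf, tens)
  rf2 <- fit_rf_outcome(tens, oc, seed = 1)
  p2 <- predict(rf2, tens)
  expect_identical(p1, p2)  # seeded retrain
  expect_true(all(p1[[1]] >= 0 & p1[[1]] <= 1))

  w <- build_lookback_windows(tens, 3)
  rfd <- fit_rf_difficulty(w, "stiffness", rc, seed = 1)
  cls <- predict(rfd, w)
  expect_true(all(cls %in% 1:3))
})

test_that("baseline predictors produce the expected degenerate outputs", {
  tens <- small_tensor()
  mean_pred <- cohort_mean_predictor(tens)
  p <- predict(mean_pred, tens)
  expect_equal(unname(p[[1]][1, ]), unname(colMeans(tens$labels)))
  expect_true(all(vapply(p, function(m) diff(range(m[, 1])) == 0,
                         logical(1))))
  maj <- majority_class_baseline(c(1L, 2L, 2L, 3L), 3L)
  expect_equal(maj$class, 2L)
  expect_equal(predict(maj, 4), rep(2L, 4))
})
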