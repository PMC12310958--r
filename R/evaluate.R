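#' Root-mean-square error and mean absolute error
#'
#' `rmse` is the square root of the average squared difference between true
#' and predicted values; `mae` the average absolute difference. Both are in
#' the units of the target.
#'
#' @param y True values.
#' @param yhat Predicted values (same length).
#' @return A single number.
#' @examples
#' rmse(c(1, 2, 3), c(2, 2, 4))  # sqrt(2/3)
#' mae(c(1, 2, 3), c(2, 2, 4))   # 2/3
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) < 1L) stop("need at least one data point", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) < 1L) stop("need at least one data point", call. = FALSE)
  mean(abs(y - yhat))
}

#' Overall accuracy of a classifier
#'
#' The ratio of correctly classified cases over the total number of cases,
#' i.e. `(TP + TN) / (TP + TN + FP + FN)` pooled over classes.
#'
#' @param y True class labels.
#' @param yhat Predicted class labels.
#' @return Accuracy in `[0, 1]`.
#' @export
overall_accuracy <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) < 1L) stop("need at least one case", call. = FALSE)
  mean(y == yhat)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' Per class, precision is `TP / (TP + FP)` and recall `TP / (TP + FN)`;
#' the F1 score is their harmonic mean, defined as 0 (with a warning) when
#' a denominator vanishes. Multi-class results are averaged over classes,
#' weighted by class support by default (`average = "macro"` gives the
#' unweighted mean).
#'
#' @param y True class labels (integer or factor).
#' @param yhat Predicted class labels.
#' @param n_classes Number of classes (default: inferred).
#' @param average `"weighted"` (default) or `"macro"`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(y, yhat, n_classes = NULL,
                     average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  y <- as.integer(y); yhat <- as.integer(yhat)
  if (is.null(n_classes)) n_classes <- max(y, yhat)
  f1k <- numeric(n_classes); support <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    tp <- sum(y == k & yhat == k)
    fp <- sum(y != k & yhat == k)
    fn <- sum(y == k & yhat != k)
    support[k] <- sum(y == k)
    if (tp + fp == 0 || tp + fn == 0) {
      if (support[k] > 0)
        warning("class ", k, " has undefined precision or recall; F1 set ",
                "to 0", call. = FALSE)
      f1k[k] <- 0
      next
    }
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    f1k[k] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  if (average == "weighted") {
    if (sum(support) == 0) return(0)
    sum(f1k * support) / sum(support)
  } else {
    if (!any(support > 0)) return(0)
    mean(f1k[support > 0])
  }
}

#' Percentage difference between true and mean predicted score
#'
#' `pd = (y - yhat_mean) / max_score`: positive values indicate the model
#' predicts under the actual discharge score, negative values over it.
#'
#' @param y True discharge score.
#' @param yhat_mean The patient's mean predicted value.
#' @param max_score Maximum achievable score of the clinical scale.
#' @return List of class `pd_result` with `y`, `yhat_mean`, `max_score`,
#'   `pd`.
#' @examples
#' percentage_difference(57, 45.6, 57)$pd  # +0.2, under-prediction
#' @export
percentage_difference <- function(y, yhat_mean, max_score) {
  if (max_score <= 0) stop("max_score must be > 0", call. = FALSE)
  structure(list(y = y, yhat_mean = yhat_mean, max_score = max_score,
                 pd = (y - yhat_mean) / max_score),
            class = "pd_result")
}

#' Assign a prediction to an MCID group
#'
#' The minimal clinically important difference is operationalized as 10% of
#' each scale. A prediction is `within` the MCID when the percentage
#' difference lies in `[-0.10, +0.10]` (boundaries inclusive),
#' `over_predicted` when pd < -0.10 and `under_predicted` when pd > +0.10.
#'
#' @param pd Percentage difference (numeric, or a `pd_result`).
#' @param mcid MCID threshold as a fraction of the scale (default 0.10).
#' @return One of `"within"`, `"over_predicted"`, `"under_predicted"`
#'   (vectorized).
#' @export
assign_mcid_group <- function(pd, mcid = 0.10) {
  if (inherits(pd, "pd_result")) pd <- pd$pd
  if (any(!is.finite(pd))) stop("pd must be finite", call. = FALSE)
  ifelse(pd < -mcid, "over_predicted",
         ifelse(pd > mcid, "under_predicted", "within"))
}

#' Pool per-session prediction errors into per-fold metrics
#'
#' Errors are computed at every valid time-step of every patient against the
#' discharge label and pooled over sessions and patients within each test
#' fold (sessions of longer series weigh more, matching per-session error
#' accounting). Also records each patient's mean and final-session
#' prediction for the percentage-difference analysis.
#'
#' @param predictions Named list (by patient id) of `m x 3` per-step
#'   prediction matrices (normalized scale).
#' @param labels Matrix of normalized discharge labels with patient ids as
#'   row names.
#' @param folds A [make_cv_folds()] plan, or a named list of patient-id
#'   vectors.
#' @return Data frame with one row per (fold, scale, metric); attributes
#'   `patient_mean` and `patient_final` hold per-patient summary
#'   predictions.
#' @export
aggregate_session_errors <- function(predictions, labels, folds) {
  if (inherits(folds, "fold_plan")) folds <- folds$folds
  scales <- c("arat", "fma", "mi")
  rows <- list()
  pm <- list(); pf <- list()
  for (fname in names(folds)) {
    ids <- intersect(folds[[fname]], names(predictions))
    if (length(ids) == 0L)
      stop("fold ", fname, " has no evaluated patients", call. = FALSE)
    for (s in seq_along(scales)) {
      yy <- list(); hh <- list()
      for (pid in ids) {
        p <- predictions[[pid]][, s]
        yy[[pid]] <- rep(labels[pid, s], length(p))
        hh[[pid]] <- p
      }
      y <- unlist(yy); h <- unlist(hh)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fname, scale = scales[s],
        rmse = rmse(y, h), mae = mae(y, h))
    }
    for (pid in ids) {
      pm[[pid]] <- colMeans(predictions[[pid]])
      pf[[pid]] <- predictions[[pid]][nrow(predictions[[pid]]), ]
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "patient_mean") <- do.call(rbind, pm)
  attr(out, "patient_final") <- do.call(rbind, pf)
  out
}

#' Cross-validated evaluation of the outcome models
#'
#' For each fold of the shared patient-level plan: fits the normalizer on
#' the training patients only, assembles train/test tensors, trains the
#' recurrent predictor, the cohort-mean baseline and (optionally) the
#' random-forest baseline on identical data, and pools per-session test
#' errors. Percentage differences and MCID groups are derived from each
#' test patient's mean prediction.
#'
#' @param prepared A `prepared_cohort`.
#' @param folds A `fold_plan` over the prepared patients.
#' @param config An [outcome_model_config()].
#' @param with_rf Train the random-forest baseline too (default TRUE).
#' @param rf_cfg An `rf_config("outcome")`.
#' @param schema Feature schema.
#' @return Object of class `outcome_eval` with `metrics` (long data frame:
#'   model, fold, scale, rmse, mae), `pd` (per patient and scale), `mcid`
#'   groups, and the per-model pooled predictions.
#' @export
evaluate_outcome_cv <- function(prepared, folds,
                                config = outcome_model_config(),
                                with_rf = TRUE,
                                rf_cfg = rf_config("outcome"),
                                schema = feature_schema()) {
  stopifnot(inherits(folds, "fold_plan"))
  all_preds <- list(lstm = list(), mean = list(), rf = list())
  fold_of <- list()
  for (fname in names(folds$folds)) {
    test_ids <- folds$folds[[fname]]
    train_ids <- setdiff(prepared$patients$patient_id, test_ids)
    train_sess <- prepared$sessions[prepared$sessions$patient_id %in%
                                      train_ids, , drop = FALSE]
    train_pat <- prepared$patients[prepared$patients$patient_id %in%
                                     train_ids, , drop = FALSE]
    state <- fit_normalizer(train_sess, train_pat, prepared$features,
                            prepared$n_games)
    train_tensor <- assemble_cohort_tensor(prepared, state, train_ids,
                                           prepared$target, schema)
    test_tensor <- assemble_cohort_tensor(prepared, state, test_ids,
                                          prepared$target, schema)
    fit <- outcome_lstm(train_tensor, config)
    p <- predict(fit, test_tensor)
    all_preds$lstm[names(p)] <- p
    base <- cohort_mean_predictor(train_tensor)
    p <- predict(base, test_tensor)
    all_preds$mean[names(p)] <- p
    if (with_rf) {
      rf <- fit_rf_outcome(train_tensor, rf_cfg, seed = config$seed)
      p <- predict(rf, test_tensor)
      all_preds$rf[names(p)] <- p
    }
    fold_of[[fname]] <- test_ids
  }
  labels_all <- local({
    pat <- prepared$patients
    m <- t(vapply(seq_len(nrow(pat)), function(i)
      normalize_clinical_scores(list(arat = pat$arat_t1[i],
                                     fma = pat$fma_t1[i],
                                     mi = pat$mi_t1[i])), numeric(3)))
    rownames(m) <- pat$patient_id
    colnames(m) <- c("arat", "fma", "mi")
    m
  })
  metrics <- list(); pd_rows <- list()
  for (model in names(all_preds)) {
    if (length(all_preds[[model]]) == 0L) next
    agg <- aggregate_session_errors(all_preds[[model]], labels_all, fold_of)
    metrics[[model]] <- cbind(model = model, agg)
    means <- attr(agg, "patient_mean")
    mx <- clinical_scale_max()
    for (s in colnames(means)) {
      pd <- labels_all[rownames(means), s] - means[, s]
      pd_rows[[paste(model, s)]] <- data.frame(
        model = model, patient_id = rownames(means), scale = s, pd = pd,
        group = assign_mcid_group(pd), row.names = NULL)
    }
  }
  structure(list(metrics = do.call(rbind, c(metrics,
                                            make.row.names = FALSE)),
                 pd = do.call(rbind, c(pd_rows, make.row.names = FALSE)),
                 predictions = all_preds, labels = labels_all,
                 folds = folds),
            class = "outcome_eval")
}

#' Cross-validated evaluation of the difficulty recommenders
#'
#' Per robot parameter and fold: fits the normalizer on training patients,
#' builds lookback windows with the parameter's own lookback, trains the
#' recurrent classifier, the majority-class baseline and (optionally) the
#' random-forest classifier on identical windows, and scores overall
#' accuracy and F1 on the held-out windows.
#'
#' @param prepared A `prepared_cohort`.
#' @param folds A `fold_plan` (shared with the outcome task).
#' @param params Parameters to evaluate (default all three).
#' @param configs Named list of [difficulty_model_config()]s.
#' @param with_rf Train the random-forest baseline too.
#' @param rf_cfg An `rf_config("recommendation")`.
#' @param schema Feature schema.
#' @return Object of class `difficulty_eval` with `metrics` (model, fold,
#'   param, oa, f1).
#' @export
evaluate_difficulty_cv <- function(prepared, folds,
                                   params = c("stiffness", "weight",
                                              "viscosity"),
                                   configs = NULL,
                                   with_rf = TRUE,
                                   rf_cfg = rf_config("recommendation"),
                                   schema = feature_schema()) {
  stopifnot(inherits(folds, "fold_plan"))
  if (is.null(configs))
    configs <- stats::setNames(lapply(params, difficulty_model_config),
                               params)
  rows <- list()
  for (fname in names(folds$folds)) {
    test_ids <- folds$folds[[fname]]
    train_ids <- setdiff(prepared$patients$patient_id, test_ids)
    train_sess <- prepared$sessions[prepared$sessions$patient_id %in%
                                      train_ids, , drop = FALSE]
    train_pat <- prepared$patients[prepared$patients$patient_id %in%
                                     train_ids, , drop = FALSE]
    state <- fit_normalizer(train_sess, train_pat, prepared$features,
                            prepared$n_games)
    train_tensor <- assemble_cohort_tensor(prepared, state, train_ids,
                                           prepared$target, schema)
    test_tensor <- assemble_cohort_tensor(prepared, state, test_ids,
                                          prepared$target, schema)
    for (param in params) {
      cfg <- configs[[param]]
      train_win <- build_lookback_windows(train_tensor, cfg$lookback)
      test_win <- build_lookback_windows(test_tensor, cfg$lookback)
      y <- test_win$labels[[param]]
      fit <- difficulty_lstm(train_win, cfg)
      pred <- predict(fit, test_win)$class
      rows[[length(rows) + 1L]] <- data.frame(
        model = "lstm", fold = fname, param = param,
        oa = overall_accuracy(y, pred),
        f1 = f1_score(y, pred, cfg$n_classes))
      maj <- majority_class_baseline(train_win$labels[[param]],
                                     cfg$n_classes)
      mpred <- predict(maj, length(y))
      rows[[length(rows) + 1L]] <- data.frame(
        model = "majority", fold = fname, param = param,
        oa = overall_accuracy(y, mpred),
        f1 = f1_score(y, mpred, cfg$n_classes))
      if (with_rf) {
        rf <- fit_rf_difficulty(train_win, param, rf_cfg, seed = cfg$seed)
        rpred <- predict(rf, test_win)
        rows[[length(rows) + 1L]] <- data.frame(
          model = "rf", fold = fname, param = param,
          oa = overall_accuracy(y, rpred),
          f1 = f1_score(y, rpred, cfg$n_classes))
      }
    }
  }
  structure(list(metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
                 folds = folds, configs = configs),
            class = "difficulty_eval")
}

#' Aggregate per-fold metrics into a report table
#'
#' Produces the Mean±Std and Min/Max layout per model and metric.
#'
#' @param metrics Long per-fold metric data frame (from the evaluators).
#' @param by Grouping columns (e.g. `c("model", "scale")`).
#' @param value Metric column names.
#' @return Data frame with mean, sd, min, max per group and metric.
#' @export
summarize_eval_metrics <- function(metrics, by, value) {
  key <- interaction(metrics[by], drop = TRUE, sep = " / ")
  rows <- lapply(levels(key), function(k) {
    sub <- metrics[key == k, , drop = FALSE]
    do.call(rbind, lapply(value, function(v) data.frame(
      group = k, metric = v, mean = mean(sub[[v]]),
      sd = stats::sd(sub[[v]]), min = min(sub[[v]]), max = max(sub[[v]]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation feature importance
#'
#' Importance of each of the 36 schema features measured as the increase in
#' prediction error (RMSE for the outcome model, 1 - accuracy for the
#' recommenders) after randomly shuffling the feature's values across
#' samples. By default the whole trajectory of a feature is permuted
#' between samples, preserving within-series temporal coherence
#' (`per_timestep = TRUE` shuffles each time-step independently instead).
#' Degradations are averaged over `n_repeats` permutations, negative values
#' clipped to 0, and the result normalized to sum to one.
#'
#' @param model An `outcome_lstm`/`rf_outcome` (with `data` a
#'   `cohort_tensor`) or a `difficulty_lstm`/`rf_difficulty` (with `data` a
#'   `lookback_dataset`).
#' @param data Evaluation data matching the model.
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Seed for the permutations.
#' @param per_timestep Shuffle each time-step independently.
#' @return Object of class `perm_importance`: named numeric vector of
#'   normalized importances (attribute `raw` keeps the unclipped
#'   degradations and `baseline` the unpermuted metric).
#' @export
permutation_importance <- function(model, data, n_repeats = 10L, seed = 1L,
                                   per_timestep = FALSE) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  if (inherits(data, "cohort_tensor")) {
    score <- function(tensor) {
      preds <- predict(model, tensor)
      y <- list(); h <- list()
      for (pid in names(preds)) {
        m <- nrow(preds[[pid]])
        y[[pid]] <- matrix(tensor$labels[pid, ], nrow = m, ncol = 3,
                           byrow = TRUE)
        h[[pid]] <- preds[[pid]]
      }
      rmse(unlist(y), unlist(h))
    }
    values <- data$values
    n <- dim(values)[1]
    feats <- data$schema$columns
    permute <- function(j) {
      d2 <- data
      if (per_timestep) {
        for (t in seq_len(dim(values)[2]))
          d2$values[, t, j] <- values[sample(n), t, j]
      } else {
        d2$values[, , j] <- values[sample(n), , j]
      }
      d2
    }
  } else if (inherits(data, "lookback_dataset")) {
    param <- model$config$param
    if (is.null(param)) param <- model$param  # rf_difficulty
    y <- data$labels[[param]]
    score <- function(d) {
      p <- if (inherits(model, "rf_difficulty")) predict(model, d)
           else predict(model, d)$class
      1 - overall_accuracy(y, p)
    }
    values <- data$x
    n <- dim(values)[1]
    feats <- data$schema$columns
    permute <- function(j) {
      d2 <- data
      if (per_timestep) {
        for (t in seq_len(dim(values)[2]))
          d2$x[, t, j] <- values[sample(n), t, j]
      } else {
        d2$x[, , j] <- values[sample(n), , j]
      }
      d2
    }
  } else stop("unsupported data type", call. = FALSE)

  baseline <- score(data)
  raw <- vapply(seq_along(feats), function(j)
    mean(vapply(seq_len(n_repeats), function(r) score(permute(j)) - baseline,
                numeric(1))), numeric(1))
  names(raw) <- feats
  imp <- pmax(raw, 0)
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  structure(imp, raw = raw, baseline = baseline, class = "perm_importance")
}

#' @export
print.perm_importance <- function(x, n = 10L, ...) {
  cat("Permutation importance (top ", n, " of ", length(x),
      " features; baseline metric ", signif(attr(x, "baseline"), 4),
      "):\n", sep = "")
  top <- sort(unclass(x), decreasing = TRUE)[seq_len(min(n, length(x)))]
  for (i in seq_along(top))
    cat(sprintf("  %-26s %.4f\n", names(top)[i], top[i]))
  invisible(x)
}

#' Top features by permutation importance
#'
#' @param importance A `perm_importance`.
#' @param n How many (default 10).
#' @return Named numeric vector, decreasing.
#' @export
top_features <- function(importance, n = 10L) {
  sort(unclass(importance), decreasing = TRUE)[seq_len(min(n,
                                                       length(importance)))]
}

#' Paired comparison of per-fold metrics between two models
#'
#' A paired two-sided Wilcoxon signed-rank test over fold-level metric
#' pairs, reported with the descriptive mean difference. The choice of test
#' is a package convention (the comparison protocol itself does not
#' prescribe one).
#'
#' @param metric_a,metric_b Per-fold metric vectors (paired by fold).
#' @return List with `p_value`, `mean_diff`, `method`.
#' @export
compare_models <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("fold metric vectors must be paired", call. = FALSE)
  d <- metric_a - metric_b
  if (all(d == 0)) {
    warning("all paired metrics tied; p-value degenerate at 1",
            call. = FALSE)
    return(list(p_value = 1, mean_diff = 0,
                method = "Wilcoxon signed rank (degenerate)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(metric_a, metric_b,
                                            paired = TRUE, exact = TRUE))
  list(p_value = wt$p.value, mean_diff = mean(d), method = wt$method)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param eval_outcome An `outcome_eval` (or NULL).
#' @param eval_difficulty A `difficulty_eval` (or NULL).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(eval_outcome = NULL, eval_difficulty = NULL,
                              dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  if (!is.null(eval_outcome)) {
    utils::write.csv(eval_outcome$metrics,
                     file.path(dir, "outcome_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summarize_eval_metrics(eval_outcome$metrics,
                                            c("model", "scale"),
                                            c("rmse", "mae")),
                     file.path(dir, "outcome_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(eval_outcome$pd, file.path(dir, "pd_groups.csv"),
                     row.names = FALSE)
    paths <- c(paths, file.path(dir, c("outcome_metrics.csv",
                                       "outcome_summary.csv",
                                       "pd_groups.csv")))
  }
  if (!is.null(eval_difficulty)) {
    utils::write.csv(eval_difficulty$metrics,
                     file.path(dir, "difficulty_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summarize_eval_metrics(eval_difficulty$metrics,
                                            c("model", "param"),
                                            c("oa", "f1")),
                     file.path(dir, "difficulty_summary.csv"),
                     row.names = FALSE)
    paths <- c(paths, file.path(dir, c("difficulty_metrics.csv",
                                       "difficulty_summary.csv")))
  }
  invisible(paths)
}
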