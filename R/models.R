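#' Configuration of the clinical outcome predictor
#'
#' Defaults follow the tuned architecture: six LSTM layers of 32 units with
#' tanh gate activations, a 20% dropout layer after each recurrent layer, a
#' time-distributed dense head emitting the three normalized scores at every
#' time-step, masked mean-squared-error loss, RMSprop with initial learning
#' rate 0.1 and batch size 1 (patient-by-patient updates). If training
#' diverges (non-finite loss) at the initial rate, the fit is retried once
#' at `fallback_lr`.
#'
#' @param n_layers Number of stacked LSTM layers.
#' @param units Cell units per layer.
#' @param dropout_rate Dropout rate after each recurrent layer.
#' @param optimizer `"rmsprop"` or `"adam"`.
#' @param learning_rate Initial learning rate.
#' @param fallback_lr Learning rate used on a divergence retry.
#' @param batch_size Sequences per gradient update.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience on the monitored loss.
#' @param val_frac Fraction of training patients held out to monitor early
#'   stopping (0 monitors the training loss).
#' @param clipnorm Global gradient-norm clip (0 disables).
#' @param seed Seed for weight initialization, dropout and shuffling.
#' @param min_epochs Burn-in epochs before early stopping engages (the
#'   monitored loss is unreliable near initialization).
#' @param lr_decay_every Step-decay interval in epochs (0 disables the
#'   schedule).
#' @param lr_decay_factor Multiplicative decay applied every
#'   `lr_decay_every` epochs.
#' @param n_restarts Maximum number of re-initializations when a fit
#'   degenerates to the cohort mean (best monitored MSE not meaningfully
#'   below the label-variance floor); 1 disables restarts.
#' @param n_ensemble Number of independently initialized members whose
#'   predictions are averaged (variance reduction for a deep recurrent
#'   stack on a small cohort); 1 fits a single model.
#' @return List of class `outcome_model_config`.
#' @seealso [stable_outcome_config()] for the training profile recommended
#'   with this package's recurrent engine.
#' @export
outcome_model_config <- function(n_layers = 6L, units = 32L,
                                 dropout_rate = 0.2,
                                 optimizer = "rmsprop",
                                 learning_rate = 0.1,
                                 fallback_lr = 0.001,
                                 batch_size = 1L,
                                 max_epochs = 300L, patience = 20L,
                                 val_frac = 0.15, clipnorm = 1.0,
                                 min_epochs = 30L,
                                 lr_decay_every = 0L, lr_decay_factor = 0.3,
                                 seed = 42L, n_restarts = 3L,
                                 n_ensemble = 1L) {
  stopifnot(n_layers >= 1L, units >= 1L,
            dropout_rate >= 0, dropout_rate < 1,
            optimizer %in% c("rmsprop", "adam"),
            learning_rate >= 0, batch_size >= 1L, n_restarts >= 1L,
            n_ensemble >= 1L)
  structure(as.list(environment()), class = "outcome_model_config")
}

#' Recommended outcome-model training profile for this engine
#'
#' Same architecture as [outcome_model_config()] (six LSTM layers of 32
#' units, dropout 0.2, per-step dense head) but with the optimizer settings
#' under which this package's double-precision recurrent engine reliably
#' learns patient-specific trajectories: Adam with a small step size, a
#' long early-stopping patience and a small prediction-averaging ensemble.
#' At the default initial step of 0.1 the masked MSE settles at the
#' label-variance floor (the model degenerates to the cohort mean); see the
#' methods vignette for the analysis.
#'
#' @param learning_rate Step size (default 3e-4).
#' @param max_epochs,patience,seed As in [outcome_model_config()].
#' @return List of class `outcome_model_config`.
#' @export
stable_outcome_config <- function(learning_rate = 3e-4, max_epochs = 300L,
                                  patience = 300L, seed = 42L,
                                  n_ensemble = 3L) {
  outcome_model_config(optimizer = "adam", learning_rate = learning_rate,
                       fallback_lr = learning_rate, max_epochs = max_epochs,
                       patience = patience, val_frac = 0.2, seed = seed,
                       n_restarts = 1L, n_ensemble = n_ensemble)
}

#' Fit the per-time-step clinical outcome predictor
#'
#' Trains a stacked LSTM that maps each patient's harmonized 64 x 36 series
#' to per-time-step predictions of the three normalized discharge scores
#' (ARAT, FMA, MI). The discharge triple is used as the label at every valid
#' time-step; padded rows are masked out of the loss entirely (only the
#' valid prefix of each series enters the network, which for end-padding is
#' exactly the masked loss).
#'
#' @param tensor A `cohort_tensor` of training patients.
#' @param config An [outcome_model_config()].
#' @return Object of class `outcome_lstm` with the fitted weights, training
#'   history and config.
#' @seealso [predict.outcome_lstm()]
#' @export
outcome_lstm <- function(tensor, config = outcome_model_config()) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  xs <- ys <- list()
  for (i in seq_along(tensor$patient_ids)) {
    m <- sum(tensor$mask[i, ])
    if (m == 0L) next
    xs[[length(xs) + 1L]] <- prefix_matrix(tensor, i)
    ys[[length(ys) + 1L]] <- matrix(tensor$labels[i, ], nrow = m, ncol = 3,
                                    byrow = TRUE)
  }
  units <- rep(as.integer(config$units), config$n_layers)
  # degenerate-fit floor: the MSE a constant (cohort-mean) predictor attains
  lbl <- do.call(rbind, ys)
  trivial_mse <- mean(sweep(lbl, 2, colMeans(lbl))^2)
  run <- function(lr, seed) {
    cpp_lstm_train(xs, ys, integer(length(xs)), "regression", units,
                   config$dropout_rate, config$optimizer, lr,
                   config$batch_size, config$max_epochs, config$patience,
                   config$val_frac, 3L, seed, config$clipnorm,
                   config$min_epochs, config$lr_decay_every,
                   config$lr_decay_factor)
  }
  lr_used <- config$learning_rate
  fit_one <- function(base_seed) {
    best <- NULL
    for (r in seq_len(config$n_restarts)) {
      cand <- run(lr_used, base_seed + (r - 1L) * 101L)
      if (isTRUE(cand$diverged) && config$fallback_lr < lr_used) {
        warning("training diverged at learning rate ", lr_used,
                "; retrying at ", config$fallback_lr, call. = FALSE)
        lr_used <<- config$fallback_lr
        cand <- run(lr_used, base_seed + (r - 1L) * 101L)
      }
      if (isTRUE(cand$diverged))
        stop("training diverged even at the fallback learning rate; ",
             "consider lowering it further", call. = FALSE)
      if (is.null(best) || cand$best_monitor < best$best_monitor)
        best <- cand
      # stop restarting once clearly below the constant-predictor floor
      if (best$best_monitor < 0.5 * trivial_mse) break
    }
    best
  }
  members <- lapply(seq_len(config$n_ensemble), function(j)
    fit_one(config$seed + (j - 1L) * 1009L))
  # averaging with a member stuck at the mean only dilutes the ensemble
  monitors <- vapply(members, function(m) m$best_monitor, numeric(1))
  good <- monitors < 0.9 * trivial_mse
  if (any(good)) members <- members[good]
  fit <- members[[1L]]
  structure(list(weights = fit$weights,
                 members = lapply(members, `[[`, "weights"),
                 history = fit$history,
                 monitors = monitors,
                 diverged = fit$diverged, best_epoch = fit$best_epoch,
                 lr_used = lr_used, config = config,
                 schema = tensor$schema,
                 n_train = length(xs)),
            class = "outcome_lstm")
}

#' Predict discharge scores at every valid time-step
#'
#' @param object An `outcome_lstm`.
#' @param tensor A `cohort_tensor` (any patients on the same schema).
#' @param denormalize If `TRUE`, scale the `[0, 1]` outputs back to the
#'   clinical scales (ARAT 0-57, FMA 0-66, MI 0-100).
#' @param ... Unused.
#' @return Named list, per patient, of `m x 3` matrices (valid time-steps
#'   only; padded rows are never predicted).
#' @export
predict.outcome_lstm <- function(object, tensor, denormalize = FALSE, ...) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  if (!identical(tensor$schema$columns, object$schema$columns))
    stop("tensor schema does not match the model's schema", call. = FALSE)
  keep <- which(rowSums(tensor$mask) > 0)
  xs <- lapply(keep, function(i) prefix_matrix(tensor, i))
  members <- if (is.null(object$members)) list(object$weights)
             else object$members
  preds <- cpp_lstm_predict(members[[1L]], xs, "regression")
  if (length(members) > 1L) {
    for (w in members[-1L]) {
      more <- cpp_lstm_predict(w, xs, "regression")
      preds <- Map(`+`, preds, more)
    }
    preds <- lapply(preds, `/`, length(members))
  }
  preds <- lapply(preds, function(p) {
    p <- pmin(pmax(p, 0), 1)  # pmax(p, .) keeps dim attributes
    colnames(p) <- c("arat", "fma", "mi")
    if (denormalize) p <- sweep(p, 2, clinical_scale_max(), `*`)
    p
  })
  names(preds) <- tensor$patient_ids[keep]
  preds
}

#' @export
print.outcome_lstm <- function(x, ...) {
  cat("Clinical outcome predictor (stacked LSTM)\n",
      "  layers: ", x$config$n_layers, " x ", x$config$units,
      " units, dropout ", x$config$dropout_rate, "\n",
      "  optimizer: ", x$config$optimizer, " (lr ", x$lr_used,
      "), batch size ", x$config$batch_size, "\n",
      "  trained on ", x$n_train, " patients; best epoch ", x$best_epoch,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.outcome_lstm <- function(object, ...) {
  h <- object$history
  cat("Clinical outcome predictor\n")
  print(object)
  cat("  epochs run: ", nrow(h), "; final train loss ",
      signif(h$train_loss[nrow(h)], 4), "; best monitored loss ",
      signif(min(h$monitor_loss), 4), "\n", sep = "")
  invisible(object)
}

#' @export
plot.outcome_lstm <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "masked MSE", ...)
  graphics::lines(h$epoch, h$monitor_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "monitor"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Per-parameter configuration of the difficulty recommenders
#'
#' Tuned settings per robot parameter: stiffness uses a two-layer stacked
#' LSTM of 64 units with lookback 3 and dropout 0.1; weight a single layer
#' of 32 units, lookback 3, dropout 0.2; viscosity a single layer of 64
#' units, lookback 5, dropout 0.2. All use tanh activations, Adam and batch
#' size 256, with a softmax class-probability head trained with categorical
#' cross-entropy.
#'
#' @param param `"stiffness"`, `"weight"` or `"viscosity"`.
#' @param max_epochs,patience,val_frac,learning_rate,clipnorm,min_epochs,seed
#'   Training controls (the architecture fields come from the tuned
#'   settings).
#' @return List of class `difficulty_model_config`.
#' @export
difficulty_model_config <- function(param = c("stiffness", "weight",
                                              "viscosity"),
                                    max_epochs = 200L, patience = 20L,
                                    val_frac = 0.15,
                                    learning_rate = 0.001,
                                    clipnorm = 1.0, min_epochs = 10L,
                                    seed = 42L) {
  param <- match.arg(param)
  arch <- switch(param,
    stiffness = list(units = c(64L, 64L), lookback = 3L, dropout_rate = 0.1,
                     n_classes = 3L),
    weight = list(units = 32L, lookback = 3L, dropout_rate = 0.2,
                  n_classes = 3L),
    viscosity = list(units = 64L, lookback = 5L, dropout_rate = 0.2,
                     n_classes = 2L))
  structure(c(list(param = param, optimizer = "adam", batch_size = 256L,
                   max_epochs = as.integer(max_epochs),
                   patience = as.integer(patience), val_frac = val_frac,
                   learning_rate = learning_rate, clipnorm = clipnorm,
                   min_epochs = as.integer(min_epochs),
                   seed = as.integer(seed)),
              arch),
            class = "difficulty_model_config")
}

#' Fit a next-session difficulty recommender
#'
#' Trains an LSTM classifier that consumes the last `lookback` time-points
#' of a patient's series and predicts the therapist's level choice for one
#' robot parameter at the next session.
#'
#' @param windows A `lookback_dataset` built with the parameter's lookback
#'   (see [build_lookback_windows()] and [difficulty_model_config()]).
#' @param config A [difficulty_model_config()].
#' @return Object of class `difficulty_lstm`.
#' @export
difficulty_lstm <- function(windows,
                            config = difficulty_model_config("stiffness")) {
  stopifnot(inherits(windows, "lookback_dataset"))
  if (windows$lookback != config$lookback)
    stop("window length ", windows$lookback, " does not match the ",
         config$param, " model's lookback ", config$lookback, call. = FALSE)
  n <- dim(windows$x)[1]
  if (n == 0L) stop("empty window set", call. = FALSE)
  xs <- lapply(seq_len(n), function(j) window_matrix(windows, j))
  labels <- windows$labels[[config$param]]
  fit <- cpp_lstm_train(xs, list(), as.integer(labels), "classification",
                        as.integer(config$units), config$dropout_rate,
                        config$optimizer, config$learning_rate,
                        config$batch_size, config$max_epochs,
                        config$patience, config$val_frac,
                        config$n_classes, config$seed, config$clipnorm,
                        config$min_epochs, 0L, 0.3)
  structure(list(weights = fit$weights, history = fit$history,
                 diverged = fit$diverged, best_epoch = fit$best_epoch,
                 config = config, schema = windows$schema,
                 n_train = n),
            class = "difficulty_lstm")
}

#' Recommend difficulty levels for the next session
#'
#' @param object A `difficulty_lstm`.
#' @param windows A `lookback_dataset` (or a single `lookback x 36` matrix).
#' @param ... Unused.
#' @return List with `prob` (windows x classes probability matrix, rows sum
#'   to 1) and `level` (recommended level labels; the most probable class by
#'   argmax, ties resolved toward the easier level).
#' @export
predict.difficulty_lstm <- function(object, windows, ...) {
  if (is.matrix(windows)) {
    if (nrow(windows) != object$config$lookback)
      stop("window has ", nrow(windows), " rows; the ", object$config$param,
           " model needs lookback ", object$config$lookback, call. = FALSE)
    xs <- list(windows)
  } else {
    stopifnot(inherits(windows, "lookback_dataset"))
    if (windows$lookback != object$config$lookback)
      stop("window length does not match the model lookback", call. = FALSE)
    xs <- lapply(seq_len(dim(windows$x)[1]),
                 function(j) window_matrix(windows, j))
  }
  probs <- cpp_lstm_predict(object$weights, xs, "classification")
  prob <- do.call(rbind, lapply(probs, as.numeric))
  levs <- robot_level_sets()[[object$config$param]]
  colnames(prob) <- levs
  cls <- apply(prob, 1, which.max)  # first max = easier level on ties
  list(prob = prob, class = as.integer(cls), level = levs[cls])
}

#' @export
print.difficulty_lstm <- function(x, ...) {
  cat("Difficulty recommender (", x$config$param, "): ",
      length(x$config$units), " LSTM layer(s) of ",
      paste(x$config$units, collapse = "/"), " units, lookback ",
      x$config$lookback, ", dropout ", x$config$dropout_rate,
      ", ", x$config$n_classes, " classes\n",
      "  trained on ", x$n_train, " windows; best epoch ", x$best_epoch,
      "\n", sep = "")
  invisible(x)
}

#' Recommend the three robot parameters for one upcoming session
#'
#' Applies the three fitted recommenders to a patient's recent time-steps.
#' Each model consumes its own lookback; `recent` must have at least the
#' largest lookback's rows (the last rows are used).
#'
#' @param models Named list with `stiffness`, `weight`, `viscosity`
#'   `difficulty_lstm` fits.
#' @param recent Matrix of the patient's most recent normalized time-steps
#'   (rows = time, columns = 36 schema features).
#' @return Named list per parameter with `prob` and `level`.
#' @export
recommend_parameters <- function(models, recent) {
  lapply(models, function(m) {
    lb <- m$config$lookback
    if (nrow(recent) < lb)
      stop("need at least ", lb, " recent time-steps for the ",
           m$config$param, " model", call. = FALSE)
    win <- recent[(nrow(recent) - lb + 1L):nrow(recent), , drop = FALSE]
    p <- predict(m, win)
    list(prob = p$prob[1, ], level = p$level[1])
  })
}

#' Cohort-mean baseline for outcome prediction
#'
#' Predicts the training cohort's mean normalized discharge triple at every
#' time-step of every patient; the trivial reference the recurrent model
#' must beat.
#'
#' @param tensor Training `cohort_tensor`.
#' @return Object of class `cohort_mean_predictor`.
#' @export
cohort_mean_predictor <- function(tensor) {
  structure(list(mean = colMeans(tensor$labels)),
            class = "cohort_mean_predictor")
}

#' @export
predict.cohort_mean_predictor <- function(object, tensor, ...) {
  keep <- which(rowSums(tensor$mask) > 0)
  preds <- lapply(keep, function(i) {
    m <- sum(tensor$mask[i, ])
    matrix(object$mean, nrow = m, ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("arat", "fma", "mi")))
  })
  names(preds) <- tensor$patient_ids[keep]
  preds
}

#' Majority-class baseline for difficulty recommendation
#'
#' @param labels Integer class labels of the training windows.
#' @param n_classes Number of classes.
#' @return Object of class `majority_class_baseline`.
#' @export
majority_class_baseline <- function(labels, n_classes) {
  counts <- tabulate(labels, nbins = n_classes)
  structure(list(class = which.max(counts), counts = counts),
            class = "majority_class_baseline")
}

#' @export
predict.majority_class_baseline <- function(object, n, ...) {
  rep(object$class, n)
}

#' Random-forest baseline hyperparameters
#'
#' Fixed baseline settings: the outcome regressor uses 300 trees, max
#' depth 10, minimum 5 samples to split a node and minimum 20 samples per
#' leaf; the recommendation classifiers use 350, 15, 5 and 5.
#'
#' @param task `"outcome"` or `"recommendation"`.
#' @return List of class `rf_config` with `num_trees`, `max_depth`,
#'   `min_samples_split`, `min_samples_leaf`.
#' @export
rf_config <- function(task = c("outcome", "recommendation")) {
  task <- match.arg(task)
  cfg <- if (task == "outcome")
    list(num_trees = 300L, max_depth = 10L, min_samples_split = 5L,
         min_samples_leaf = 20L)
  else
    list(num_trees = 350L, max_depth = 15L, min_samples_split = 5L,
         min_samples_leaf = 5L)
  structure(c(cfg, task = task), class = "rf_config")
}

# valid prefix of patient i as an m x 36 matrix (dimension-drop safe)
prefix_matrix <- function(tensor, i) {
  m <- sum(tensor$mask[i, ])
  v <- tensor$values[i, seq_len(m), , drop = FALSE]
  dim(v) <- c(m, dim(tensor$values)[3])
  colnames(v) <- tensor$schema$columns
  v
}

# window j of a lookback dataset as an L x 36 matrix
window_matrix <- function(windows, j) {
  v <- windows$x[j, , , drop = FALSE]
  dim(v) <- dim(windows$x)[2:3]
  colnames(v) <- windows$schema$columns
  v
}

# per-time-step design matrix of all valid rows of a tensor
tensor_to_rows <- function(tensor) {
  rows <- list(); labs <- list(); pid <- list()
  for (i in seq_along(tensor$patient_ids)) {
    m <- sum(tensor$mask[i, ])
    if (m == 0L) next
    rows[[length(rows) + 1L]] <- prefix_matrix(tensor, i)
    labs[[length(labs) + 1L]] <- matrix(tensor$labels[i, ], nrow = m,
                                        ncol = 3, byrow = TRUE)
    pid[[length(pid) + 1L]] <- rep(tensor$patient_ids[i], m)
  }
  x <- do.call(rbind, rows)
  colnames(x) <- tensor$schema$columns
  list(x = x, y = do.call(rbind, labs),
       patient_id = unlist(pid))
}

#' Fit the random-forest outcome baseline
#'
#' Three random-forest regressors (one per clinical scale) consuming the
#' per-time-step 36-feature rows and predicting the normalized discharge
#' score at each row, with the stated hyperparameters and the same fold
#' plan as the recurrent model.
#'
#' @param tensor Training `cohort_tensor`.
#' @param config An `rf_config("outcome")`.
#' @param seed Seed.
#' @return Object of class `rf_outcome` with one `ranger` fit per scale.
#' @export
fit_rf_outcome <- function(tensor, config = rf_config("outcome"),
                           seed = 42L) {
  rows <- tensor_to_rows(tensor)
  d <- as.data.frame(rows$x)
  fits <- lapply(1:3, function(k) {
    d$.y <- rows$y[, k]
    ranger::ranger(
      dependent.variable.name = ".y", data = d,
      num.trees = config$num_trees, max.depth = config$max_depth,
      min.node.size = config$min_samples_split,
      min.bucket = config$min_samples_leaf,
      seed = seed, num.threads = 1
    )
  })
  names(fits) <- c("arat", "fma", "mi")
  structure(list(fits = fits, config = config, schema = tensor$schema),
            class = "rf_outcome")
}

#' @export
predict.rf_outcome <- function(object, tensor, ...) {
  keep <- which(rowSums(tensor$mask) > 0)
  preds <- lapply(keep, function(i) {
    m <- sum(tensor$mask[i, ])
    d <- as.data.frame(prefix_matrix(tensor, i))
    p <- vapply(object$fits, function(f)
      stats::predict(f, data = d, num.threads = 1)$predictions,
      numeric(m))
    p <- matrix(pmin(1, pmax(0, p)), nrow = m,
                dimnames = list(NULL, c("arat", "fma", "mi")))
    p
  })
  names(preds) <- tensor$patient_ids[keep]
  preds
}

#' Fit a random-forest difficulty baseline
#'
#' A random-forest classifier on the flattened `lookback x 36` windows with
#' the stated recommendation-task hyperparameters.
#'
#' @param windows Training `lookback_dataset`.
#' @param param Robot parameter to predict.
#' @param config An `rf_config("recommendation")`.
#' @param seed Seed.
#' @return Object of class `rf_difficulty`.
#' @export
fit_rf_difficulty <- function(windows, param,
                              config = rf_config("recommendation"),
                              seed = 42L) {
  n <- dim(windows$x)[1]
  x <- matrix(windows$x, nrow = n)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  d <- as.data.frame(x)
  d$.y <- factor(windows$labels[[param]],
                 levels = seq_along(robot_level_sets()[[param]]))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = config$num_trees, max.depth = config$max_depth,
    min.node.size = config$min_samples_split,
    min.bucket = config$min_samples_leaf,
    seed = seed, num.threads = 1
  )
  structure(list(fit = fit, param = param, config = config,
                 lookback = windows$lookback),
            class = "rf_difficulty")
}

#' @export
predict.rf_difficulty <- function(object, windows, ...) {
  n <- dim(windows$x)[1]
  x <- matrix(windows$x, nrow = n)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- stats::predict(object$fit, data = as.data.frame(x),
                      num.threads = 1)$predictions
  as.integer(as.character(p))
}

#' Number of trainable parameters of a fitted LSTM
#'
#' @param object An `outcome_lstm` or `difficulty_lstm`.
#' @return Integer count of weights.
#' @export
n_parameters <- function(object) {
  w <- object$weights
  n <- length(w$Wo) + length(w$bo)
  for (l in w$layers) n <- n + length(l$W) + length(l$U) + length(l$b)
  as.integer(n)
}
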