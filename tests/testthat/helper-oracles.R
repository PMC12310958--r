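# Independent brute-force references used to cross-check the implementation.

# Reference shrink: literal restatement of the pruning rules with different
# primitives (explicit data-frame scans instead of the package's vectorized
# bookkeeping).
oracle_shrink <- function(series, target, gap_tie = "small") {
  removals <- NULL
  it <- 0
  while (nrow(series) > target) {
    it <- it + 1
    day <- as.integer(as.Date(series$date))
    groups <- data.frame(date = sort(unique(day)))
    groups$n_unique <- NA_integer_
    groups$gap <- Inf
    for (k in seq_len(nrow(groups))) {
      groups$n_unique[k] <-
        length(unique(series$game_id[day == groups$date[k]]))
      gaps <- c()
      if (k > 1) gaps <- c(gaps, groups$date[k] - groups$date[k - 1])
      if (k < nrow(groups)) gaps <- c(gaps, groups$date[k + 1] - groups$date[k])
      if (length(gaps)) groups$gap[k] <- min(gaps)
    }
    # rank: unique games desc, gap (direction per gap_tie), date asc
    gkey <- if (gap_tie == "small") groups$gap else -groups$gap
    best <- groups[order(-groups$n_unique, gkey, groups$date), ][1, ]
    games_present <- sort(unique(series$game_id))
    freq <- sapply(games_present, function(g) sum(series$game_id == g))
    names(freq) <- games_present
    cand <- sort(unique(series$game_id[day == best$date]))
    cand_freq <- freq[as.character(cand)]
    game <- cand[which(cand_freq == max(cand_freq))][1]
    idx <- which(day == best$date & series$game_id == game)[1]
    removals <- rbind(removals,
                      data.frame(iteration = it, date = series$date[idx],
                                 game_id = game))
    series <- series[-idx, , drop = FALSE]
  }
  rownames(series) <- NULL
  list(series = series, removals = removals)
}

oracle_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}

oracle_mae <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - yhat[i])
  s / length(y)
}

oracle_oa <- function(y, yhat) {
  correct <- 0
  for (i in seq_along(y)) if (y[i] == yhat[i]) correct <- correct + 1
  correct / length(y)
}

# Weighted F1 from an explicit confusion matrix.
oracle_f1_weighted <- function(y, yhat, n_classes) {
  cm <- matrix(0, n_classes, n_classes)
  for (i in seq_along(y)) cm[y[i], yhat[i]] <- cm[y[i], yhat[i]] + 1
  f1 <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA
    f1[k] <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
             else 2 * prec * rec / (prec + rec)
  }
  support <- rowSums(cm)
  sum(f1 * support) / sum(support)
}

# Brute-force mutuality: count game membership one feature at a time.
oracle_mutuality <- function(masks, feature) {
  n <- 0
  for (m in masks) if (feature %in% m) n <- n + 1
  n / length(masks)
}
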