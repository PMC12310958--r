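# day offsets from either integer day numbers or ISO-8601 date strings
as_day <- function(x) {
  if (is.numeric(x)) as.integer(x) else as.integer(as.Date(x))
}

#' Zero-pad a feature matrix to the fixed series length
#'
#' Series shorter than the target grid are padded with all-zero rows at the
#' end; a validity mask marks the padding so the network can ignore it
#' during training and evaluation.
#'
#' @param values Numeric matrix, one row per real time-step.
#' @param target Target number of time-points (default 64).
#' @return List with `values` (`target` rows, real rows bit-identical on a
#'   prefix, zeros after) and `mask` (1 = real, 0 = padding).
#' @export
pad_series <- function(values, target = 64L) {
  values <- as.matrix(values)
  m <- nrow(values)
  if (m > target)
    stop("series longer than target (", m, " > ", target,
         "); use shrink_series()", call. = FALSE)
  if (m == 0L)
    warning("empty series: all rows padded (patient should have been ",
            "excluded upstream)", call. = FALSE)
  out <- matrix(0, nrow = target, ncol = ncol(values),
                dimnames = list(NULL, colnames(values)))
  mask <- integer(target)
  if (m > 0L) {
    out[seq_len(m), ] <- values
    mask[seq_len(m)] <- 1L
  }
  list(values = out, mask = mask)
}

#' Shrink an over-long series to the fixed length by date-group pruning
#'
#' Iteratively removes single sessions until the series has `target`
#' time-points. Each iteration: (1) sessions are grouped by date; (2) groups
#' are ranked by the number of unique games played within the group,
#' descending, with ties broken by the minimum day-distance to the adjacent
#' (previous/next) groups and remaining ties by earlier date; (3) the
#' per-game popularity (frequency of completed games over the patient's
#' current series) is computed; (4) from the top group, the session of the
#' currently most popular game is removed (ties toward the lowest game id);
#' all quantities are recomputed after every removal. The procedure prunes
#' dense therapy days first while preserving game diversity, and is fully
#' deterministic.
#'
#' @param series One patient's session data frame with `date` and `game_id`;
#'   chronological order is preserved in the output.
#' @param target Target length (default 64); must be positive and smaller
#'   than the current length.
#' @param gap_tie How the adjacent-distance tie-break orders equal-sized
#'   groups: `"small"` (default) ranks the group in the denser region first,
#'   `"large"` the opposite.
#' @return List with `series` (exactly `target` rows) and `removals`, a data
#'   frame `(iteration, date, game_id)` logging every removed session.
#' @export
shrink_series <- function(series, target = 64L, gap_tie = c("small", "large")) {
  gap_tie <- match.arg(gap_tie)
  target <- as.integer(target)
  if (is.na(target) || target <= 0L)
    stop("target must be a positive integer", call. = FALSE)
  if (nrow(series) <= target)
    stop("series not longer than target; use pad_series()", call. = FALSE)
  removals <- list()
  it <- 0L
  while (nrow(series) > target) {
    it <- it + 1L
    day <- as_day(series$date)
    dates <- sort(unique(day))
    n_unique <- vapply(dates, function(dt)
      length(unique(series$game_id[day == dt])), integer(1))
    gap <- rep(Inf, length(dates))
    if (length(dates) > 1L) {
      dd <- diff(dates)
      for (j in seq_along(dates)) {
        prev_gap <- if (j > 1L) dd[j - 1L] else Inf
        next_gap <- if (j < length(dates)) dd[j] else Inf
        gap[j] <- min(prev_gap, next_gap)
      }
    }
    gap_key <- if (gap_tie == "small") gap else -gap
    top <- order(-n_unique, gap_key, dates)[1L]
    top_date <- dates[top]
    freq <- table(series$game_id)
    in_group <- unique(series$game_id[day == top_date])
    f <- as.integer(freq[as.character(in_group)])
    best <- in_group[f == max(f)]
    game <- min(best)
    victim <- which(day == top_date & series$game_id == game)[1L]
    removals[[it]] <- data.frame(iteration = it,
                                 date = series$date[victim],
                                 game_id = game)
    series <- series[-victim, , drop = FALSE]
  }
  rownames(series) <- NULL
  list(series = series,
       removals = if (it > 0L) do.call(rbind, removals) else
         data.frame(iteration = integer(), date = series$date[0],
                    game_id = integer()))
}

#' Harmonize one patient's series to the fixed grid
#'
#' Applies [shrink_series()] when the series is longer than `target`,
#' otherwise leaves it unchanged; padding to `target` with masks happens
#' when the feature tensor is assembled.
#'
#' @param series One patient's session data frame.
#' @param target Target length (default 64).
#' @param gap_tie Passed to [shrink_series()].
#' @return List with `series` (at most `target` rows) and `removals`.
#' @export
harmonize_patient <- function(series, target = 64L,
                              gap_tie = c("small", "large")) {
  gap_tie <- match.arg(gap_tie)
  if (nrow(series) > target)
    shrink_series(series, target, gap_tie)
  else
    list(series = series,
         removals = data.frame(iteration = integer(), date = series$date[0],
                               game_id = integer()))
}
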