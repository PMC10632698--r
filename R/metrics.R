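# Time-based performance indicators computed from session logs: overall
# solving time (minutes), average target search time (seconds, match-3),
# processing time per item (seconds), and the improvement slope of search /
# path-completion time over the intervention (seconds per session, negative =
# improvement).

log_play_rows <- function(log, game = NULL) {
  rows <- log[log$event %in% c("level_complete", "timeout") & log$duration_s > 0, ,
              drop = FALSE]
  if (!is.null(game)) rows <- rows[rows$game == game, , drop = FALSE]
  rows
}

# Items processed in one level: gems cleared for match-3 (the level's clearing
# quota of 10 gems per object type), path cells for numberlink (full-fill:
# every board cell).
level_items <- function(game, board_size, num_objects) {
  ifelse(game == "match3", 10 * num_objects, board_size^2)
}

# Match-3 targets (matches made) in one level: the clearing quota at three
# gems per match.
level_targets <- function(num_objects) ceiling(10 * num_objects / 3)

#' Overall solving time
#'
#' Sum of level durations across the whole log, in minutes.
#'
#' @param log Session log data frame (see [simulate_intervention()]).
#' @param game Optional game filter.
#' @return Minutes of play.
#' @export
overall_solving_time <- function(log, game = NULL) {
  rows <- log_play_rows(log, game)
  if (nrow(rows) == 0) stop("empty log: no play events")
  sum(rows$duration_s) / 60
}

#' Processing time per item
#'
#' Total play duration divided by the total number of items processed (gems
#' cleared for match-3, path cells for numberlink).
#'
#' @param log Session log data frame.
#' @param game `"match3"` or `"numberlink"`.
#' @return Seconds per item.
#' @export
per_item_time <- function(log, game = c("match3", "numberlink")) {
  game <- match.arg(game)
  rows <- log_play_rows(log, game)
  items <- sum(level_items(rows$game, rows$board_size, rows$num_objects))
  if (items == 0) stop("zero items processed")
  sum(rows$duration_s) / items
}

#' Average target search time (match-3)
#'
#' Mean over levels of the level duration divided by the number of matches
#' made in it.
#'
#' @param log Session log data frame.
#' @return Seconds per target.
#' @export
avg_target_search_time <- function(log) {
  rows <- log_play_rows(log, "match3")
  if (nrow(rows) == 0) stop("no match-3 play events")
  mean(rows$duration_s / level_targets(rows$num_objects))
}

#' Improvement slope
#'
#' Ordinary least-squares slope of a per-session time series against the
#' session index, in seconds per session. Negative = improvement (times are
#' shrinking).
#'
#' @param series Data frame (or 2-column matrix) with columns `session_index`
#'   and `time_s`; at least two distinct session indices.
#' @return Slope in seconds per session.
#' @export
#' @examples
#' improvement_slope(data.frame(session_index = 1:3, time_s = c(30, 28, 26))) # -2
improvement_slope <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("session_index", "time_s") %in% names(series))) {
    names(series)[1:2] <- c("session_index", "time_s")
  }
  if (length(unique(series$session_index)) < 2) {
    stop("need at least two distinct session indices")
  }
  fit <- stats::lm(time_s ~ session_index, data = series)
  unname(stats::coef(fit)["session_index"])
}

# Per-session mean of the per-target (match-3) or per-level completion
# (numberlink) time.
session_time_series <- function(log, game) {
  rows <- log_play_rows(log, game)
  tvals <- if (game == "match3") {
    rows$duration_s / level_targets(rows$num_objects)
  } else {
    rows$duration_s
  }
  agg <- stats::aggregate(tvals, by = list(session_index = rows$session_index), mean)
  data.frame(session_index = agg$session_index, time_s = agg$x)
}

#' Per-participant, per-game performance summary
#'
#' One row per (participant, game): overall solving time in minutes, average
#' target search time in seconds (match-3 rows only), processing time per
#' item in seconds, and the improvement slope (match-3: per-target search
#' time; numberlink: level completion time) in seconds per session.
#'
#' @param log Session log data frame, possibly spanning many participants.
#' @return Data frame with columns `participant_id`, `game`,
#'   `overall_solving_time_min`, `avg_target_search_time_s`,
#'   `processing_time_per_item_s`, `improvement_slope`.
#' @export
performance_summary <- function(log) {
  combos <- unique(log_play_rows(log)[, c("participant_id", "game")])
  combos <- combos[order(combos$participant_id, combos$game), , drop = FALSE]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    id <- combos$participant_id[i]; game <- combos$game[i]
    sub <- log[log$participant_id == id, , drop = FALSE]
    series <- session_time_series(sub, game)
    data.frame(
      participant_id = id, game = game,
      overall_solving_time_min = overall_solving_time(sub, game),
      avg_target_search_time_s = if (game == "match3") {
        avg_target_search_time(sub)
      } else NA_real_,
      processing_time_per_item_s = per_item_time(sub, game),
      improvement_slope = if (length(unique(series$session_index)) >= 2) {
        improvement_slope(series)
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a performance summary as CSV
#'
#' @param summary Data frame from [performance_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
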