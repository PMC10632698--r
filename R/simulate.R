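# Synthetic players. A player's solving time grows with the difficulty level,
# shrinks with practice (exponential learning curve), and varies lognormally
# across attempts — standard response-time behaviour. The simulator stands in
# for human participants to generate training data and exercise the adaptive
# loop end to end.

#' Synthetic player profile
#'
#' @param skill Dimensionless time multiplier (> 0; smaller = faster player).
#' @param learning_rate Fractional per-session speedup in `[0, 0.1]`.
#' @param noise_sd SD of the lognormal (log-time) noise (>= 0).
#' @param seed Integer seed owned by this player.
#' @return A `player_profile` object.
#' @export
player_profile <- function(skill = 1, learning_rate = 0, noise_sd = 0, seed = 1L) {
  stop_if_not_scalar_number(skill, "skill")
  stop_if_not_scalar_number(learning_rate, "learning_rate")
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (skill <= 0) stop("skill must be positive")
  if (learning_rate < 0 || learning_rate > 0.1) {
    stop("learning_rate must lie in [0, 0.1]")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(skill = skill, learning_rate = learning_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "player_profile")
}

#' Intervention schedule
#'
#' Defaults mirror the study conditions: 8 weeks at a minimum of 3 sessions
#' per week, at most 10 minutes per game and 20 minutes of training per day.
#'
#' @param weeks Intervention length in weeks.
#' @param sessions_per_week Training sessions per week (>= 3).
#' @param per_game_cap_s Daily play cap per game, seconds.
#' @param daily_cap_s Total daily play cap, seconds.
#' @return An `intervention_schedule` object.
#' @export
intervention_schedule <- function(weeks = 8L, sessions_per_week = 3L,
                                  per_game_cap_s = 600, daily_cap_s = 1200) {
  if (sessions_per_week < 3) stop("sessions_per_week must be at least 3")
  if (per_game_cap_s <= 0 || daily_cap_s <= 0) stop("caps must be positive")
  structure(list(weeks = as.integer(weeks),
                 sessions_per_week = as.integer(sessions_per_week),
                 per_game_cap_s = per_game_cap_s, daily_cap_s = daily_cap_s),
            class = "intervention_schedule")
}

# Deterministic base solving time for a ladder level, seconds.
base_level_time <- function(level_index) 20 + 15 * (level_index - 1)

#' Simulate one solving time
#'
#' `t_m = base(level) * skill * (1 - learning_rate)^(session - 1) * exp(e)`
#' with `e ~ Normal(0, noise_sd^2)` and `base(level) = 20 + 15 * (index - 1)`
#' seconds.
#'
#' @param profile A [player_profile()].
#' @param level A `difficulty_level` (with ladder index) or integer index.
#' @param session_index Session number, 1-based.
#' @param seed Integer seed for the noise draw.
#' @return Solving time in seconds.
#' @export
#' @examples
#' simulate_solve_time(player_profile(), difficulty_level(4, 4, 1), 1, seed = 1) # 20
simulate_solve_time <- function(profile, level, session_index, seed) {
  stopifnot(inherits(profile, "player_profile"))
  idx <- if (inherits(level, "difficulty_level")) level$index else as.integer(level)
  det <- base_level_time(idx) * profile$skill *
    (1 - profile$learning_rate)^(session_index - 1)
  eps <- if (profile$noise_sd > 0) {
    with_seed(seed, stats::rnorm(1, 0, profile$noise_sd))
  } else 0
  det * exp(eps)
}

session_timestamp <- function(session_index, sessions_per_week, seconds_into_day) {
  day <- (session_index - 1) * max(1L, floor(7 / sessions_per_week))
  as.character(as.POSIXct("2023-01-02 09:00:00", tz = "UTC") +
                 day * 86400 + seconds_into_day)
}

#' Simulate a full intervention for one player
#'
#' Plays both games every session. Within a session each game is played in
#' attempts until its daily cap is exhausted: a level whose simulated time
#' exceeds the per-game cap is a timeout (the decision is forced to -1); an
#' attempt cut short only by the session's remaining budget is logged as a
#' timeout event without routing a level decision. Every completed attempt is
#' routed through the service's put-next-level endpoint, and the time models
#' are refitted after each session ("nightly") unless `refit = "none"`.
#'
#' @param profile A [player_profile()].
#' @param schedule An [intervention_schedule()].
#' @param srv An [adaptive_service()]; accumulates this player's attempts.
#' @param participant_id Participant identifier.
#' @param pretest Optional [pretest_scores()] for initial placement; without
#'   it play starts at ladder level 1.
#' @param games Games played each session.
#' @param refit `"nightly"` or `"none"`.
#' @return A session log data frame (one row per event: `timestamp`,
#'   `participant_id`, `game`, `event`, `level_index`, `board_size`,
#'   `num_objects`, `duration_s`, `decision`, `session_index`, `solved`).
#' @export
simulate_intervention <- function(profile, schedule, srv, participant_id,
                                  pretest = NULL,
                                  games = c("match3", "numberlink"),
                                  refit = c("nightly", "none")) {
  stopifnot(inherits(profile, "player_profile"),
            inherits(schedule, "intervention_schedule"),
            inherits(srv, "adaptive_service"))
  refit <- match.arg(refit)
  if (!is.null(pretest)) {
    for (g in games) put_initial_level(srv, g, participant_id, pretest)
  }
  n_sessions <- schedule$weeks * schedule$sessions_per_week
  rows <- list()
  add <- function(game, event, level, duration, decision, session, solved, t_day) {
    rows[[length(rows) + 1L]] <<- data.frame(
      timestamp = session_timestamp(session, schedule$sessions_per_week, t_day),
      participant_id = participant_id, game = game, event = event,
      level_index = if (is.null(level)) NA_integer_ else level$index,
      board_size = if (is.null(level)) NA_integer_ else level$board_size,
      num_objects = if (is.null(level)) NA_integer_ else level$num_objects,
      duration_s = duration, decision = decision,
      session_index = session, solved = solved, stringsAsFactors = FALSE)
  }
  for (session in seq_len(n_sessions)) {
    day_spent <- 0
    for (gi in seq_along(games)) {
      game <- games[gi]
      ladder <- srv$ladders[[game]]
      game_spent <- 0
      attempt_i <- 0L
      game_budget <- min(schedule$per_game_cap_s, schedule$daily_cap_s - day_spent)
      while (game_spent < game_budget) {
        attempt_i <- attempt_i + 1L
        level <- ladder_level(ladder, current_level(srv, game, participant_id))
        t_raw <- simulate_solve_time(
          profile, level, session,
          seed = derive_seed(profile$seed, session, gi, attempt_i))
        add(game, "level_start", level, 0, NA_integer_, session, NA, day_spent + game_spent)
        remaining <- game_budget - game_spent
        if (t_raw > schedule$per_game_cap_s && remaining >= schedule$per_game_cap_s) {
          # genuine per-level timeout: cap, force a retreat decision
          res <- put_next_level(srv, game, participant_id,
                                list(level_index = level$index,
                                     solving_time_s = schedule$per_game_cap_s,
                                     solved = FALSE,
                                     session_index = session),
                                cap_s = schedule$per_game_cap_s)
          game_spent <- game_spent + schedule$per_game_cap_s
          add(game, "timeout", level, schedule$per_game_cap_s, res$decision,
              session, FALSE, day_spent + game_spent)
        } else if (t_raw > remaining) {
          # out of daily budget mid-level: no decision routed
          game_spent <- game_budget
          add(game, "timeout", level, remaining, NA_integer_, session, FALSE,
              day_spent + game_spent)
        } else {
          res <- put_next_level(srv, game, participant_id,
                                list(level_index = level$index,
                                     solving_time_s = t_raw,
                                     solved = TRUE,
                                     session_index = session),
                                cap_s = schedule$per_game_cap_s)
          game_spent <- game_spent + t_raw
          add(game, "level_complete", level, t_raw, res$decision, session,
              TRUE, day_spent + game_spent)
        }
      }
      day_spent <- day_spent + game_spent
    }
    add(games[1], "session_end", NULL, 0, NA_integer_, session, NA, day_spent)
    if (refit == "nightly") refit_service(srv)
  }
  do.call(rbind, rows)
}

#' Draw a population of player profiles from the simulator priors
#'
#' Skill ~ LogNormal(0, 0.25), learning rate ~ Uniform(0, 0.04), noise SD ~
#' Uniform(0.1, 0.3); each player receives a derived child seed.
#'
#' @param n_players Number of players.
#' @param seed Integer master seed.
#' @return List of [player_profile()] objects named P01, P02, ...
#' @export
draw_player_profiles <- function(n_players, seed) {
  with_seed(seed, {
    lapply(seq_len(n_players), function(i) {
      player_profile(skill = stats::rlnorm(1, 0, 0.25),
                     learning_rate = stats::runif(1, 0, 0.04),
                     noise_sd = stats::runif(1, 0.1, 0.3),
                     seed = derive_seed(seed, i))
    })
  })
}

#' Generate a pooled training data set of attempts
#'
#' Simulates `n_players` synthetic players (profiles drawn from the priors of
#' [draw_player_profiles()]) through the full schedule against bootstrap
#' services (no pre-fitted model), pooling all attempts into one table ready
#' for [fit_time_model()].
#'
#' @param n_players Number of players (>= 1).
#' @param schedule An [intervention_schedule()].
#' @param seed Integer master seed.
#' @param config An [adaptive_config()].
#' @return An attempt-records data frame (see [attempt_records()]).
#' @export
generate_training_dataset <- function(n_players = 12L,
                                      schedule = intervention_schedule(),
                                      seed = 1L,
                                      config = adaptive_config()) {
  if (n_players < 1) stop("n_players must be at least 1")
  profiles <- draw_player_profiles(n_players, seed)
  out <- list()
  for (i in seq_len(n_players)) {
    srv <- adaptive_service(config)
    simulate_intervention(profiles[[i]], schedule, srv,
                          participant_id = sprintf("P%02d", i),
                          refit = "none")
    out[[i]] <- srv$attempts
  }
  attempt_records(do.call(rbind, out))
}

#' Write / read a session log as JSONL
#'
#' One JSON object per line with the event fields of
#' [simulate_intervention()]'s log.
#'
#' @param log Session log data frame.
#' @param path File path.
#' @return `path` (write) or the parsed data frame (read).
#' @export
write_session_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$level_index <- as.integer(out$level_index)
  out$board_size <- as.integer(out$board_size)
  out$num_objects <- as.integer(out$num_objects)
  out$session_index <- as.integer(out$session_index)
  out$decision <- as.integer(out$decision)
  out$solved <- as.logical(out$solved)
  out
}

#' Extract attempt records from a session log
#'
#' Keeps `level_complete` and decision-bearing `timeout` events, the events
#' that correspond to one attempted level.
#'
#' @param log Session log data frame.
#' @return An attempt-records data frame.
#' @export
attempts_from_log <- function(log) {
  rows <- log[log$event %in% c("level_complete", "timeout") & log$duration_s > 0, ,
              drop = FALSE]
  attempt_records(data.frame(
    participant_id = rows$participant_id, game = rows$game,
    level_index = rows$level_index, board_size = rows$board_size,
    num_objects = rows$num_objects, t_m = rows$duration_s,
    solved = rows$event == "level_complete",
    session_index = rows$session_index, timestamp = rows$timestamp,
    stringsAsFactors = FALSE))
}
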