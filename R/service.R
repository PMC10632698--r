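# In-process adaptive service. Mirrors the tablet-facing REST contract — the
# four endpoints match_three/putInitialLevel, match_three/putNextLevel,
# number_link/putInitialLevel, number_link/putNextLevel — as an R object with
# a JSON request handler, so the adaptation loop is callable without a
# network. Every request is logged.

endpoint_game <- c(match_three = "match3", number_link = "numberlink")

#' Create an adaptive difficulty service
#'
#' Holds per-game difficulty ladders, the (optionally pre-trained) solving-time
#' models, the pooled attempt store feeding the per-level sigma table, the
#' per-participant state (current level, time history), and a request log.
#'
#' @param config An [adaptive_config()].
#' @param training Optional attempt records used to pre-fit the per-game time
#'   models (see [fit_time_model()]); with fewer than 20 rows for a game the
#'   service starts on the bootstrap predictor (pooled per-level mean, falling
#'   back to the 20 + 15 * (index - 1) baseline curve).
#' @param reference Optional list of [pretest_scores()] used by initial level
#'   assignment; defaults to the embedded participant table.
#' @param s_range,g_range Ladder ranges passed to [build_ladder()].
#' @return An `adaptive_service` environment.
#' @export
adaptive_service <- function(config = adaptive_config(), training = NULL,
                             reference = NULL, s_range = 4:8, g_range = 4:8) {
  stopifnot(inherits(config, "adaptive_config"))
  srv <- new.env(parent = emptyenv())
  srv$config <- config
  srv$reference <- reference
  srv$ladders <- list(match3 = build_ladder("match3", s_range, g_range),
                      numberlink = build_ladder("numberlink", s_range, g_range))
  srv$models <- list(match3 = NULL, numberlink = NULL)
  srv$attempts <- empty_attempts()
  srv$participants <- list()
  srv$request_log <- list()
  class(srv) <- "adaptive_service"
  if (!is.null(training)) {
    training <- attempt_records(as.data.frame(training))
    srv$attempts <- rbind(srv$attempts, as.data.frame(training))
    refit_service(srv)
  }
  srv
}

#' @export
print.adaptive_service <- function(x, ...) {
  fitted <- names(Filter(Negate(is.null), x$models))
  cat(sprintf("<adaptive_service> %d stored attempt(s); models fitted: %s; %d request(s) logged\n",
              nrow(x$attempts),
              if (length(fitted)) paste(fitted, collapse = ", ") else "none",
              length(x$request_log)))
  invisible(x)
}

empty_attempts <- function() {
  data.frame(participant_id = character(), game = character(),
             level_index = integer(), board_size = integer(),
             num_objects = integer(), t_m = numeric(), solved = logical(),
             session_index = integer(), timestamp = character(),
             stringsAsFactors = FALSE)
}

participant_state <- function(srv, participant_id) {
  st <- srv$participants[[participant_id]]
  if (is.null(st)) {
    st <- list(level = list(match3 = 1L, numberlink = 1L),
               time_sum = 0, time_n = 0L)
  }
  st
}

#' Refit the service's time models from its attempt store
#'
#' Called "nightly" in the simulated intervention: the difficulty level for
#' the next day reflects the previous day's play. Fitting windows to the most
#' recent `window` attempts per game.
#'
#' @param srv An `adaptive_service`.
#' @param games Games to refit.
#' @param window Maximum number of most recent attempts used per fit.
#' @return The service, invisibly.
#' @export
refit_service <- function(srv, games = c("match3", "numberlink"), window = 600L) {
  stopifnot(inherits(srv, "adaptive_service"))
  for (g in games) {
    rows <- srv$attempts[srv$attempts$game == g, , drop = FALSE]
    if (nrow(rows) > window) rows <- utils::tail(rows, window)
    if (nrow(rows) >= 20 && length(unique(rows$level_index)) >= 2 &&
        stats::var(rows$t_m) > 0) {
      srv$models[[g]] <- fit_time_model(rows)
    }
  }
  invisible(srv)
}

# Predicted time for a participant at a level: fitted model when available,
# else bootstrap (pooled per-level mean with >= 3 observations, else the
# 20 + 15 * (index - 1) baseline curve).
service_predict <- function(srv, game, participant_id, level, session_index) {
  st <- participant_state(srv, participant_id)
  run_mean <- if (st$time_n > 0) st$time_sum / st$time_n else NULL
  model <- srv$models[[game]]
  if (!is.null(model)) {
    return(predict_time(model, level,
                        history = list(session_index = session_index,
                                       run_mean = run_mean)))
  }
  pool <- srv$attempts$t_m[srv$attempts$game == game &
                             srv$attempts$level_index == level$index]
  if (length(pool) >= 3) return(max(1, mean(pool)))
  20 + 15 * (level$index - 1)
}

log_request <- function(srv, endpoint, body, response) {
  srv$request_log[[length(srv$request_log) + 1L]] <-
    list(endpoint = endpoint, body = body, response = response)
  invisible(srv)
}

#' Assign a participant's initial level (service endpoint)
#'
#' In-process form of `<game>/putInitialLevel`: places the participant on the
#' ladder from their pretest scores (see [assign_initial_level()]) and stores
#' the placement as their current level for that game.
#'
#' @param srv An `adaptive_service`.
#' @param game `"match3"` or `"numberlink"`.
#' @param participant_id Participant identifier.
#' @param pretest A [pretest_scores()] object.
#' @return List with `level_index`.
#' @export
put_initial_level <- function(srv, game = c("match3", "numberlink"),
                              participant_id, pretest) {
  stopifnot(inherits(srv, "adaptive_service"))
  game <- match.arg(game)
  lvl <- assign_initial_level(pretest, srv$ladders[[game]], srv$reference)
  st <- participant_state(srv, participant_id)
  st$level[[game]] <- lvl$index
  srv$participants[[participant_id]] <- st
  res <- list(level_index = lvl$index)
  log_request(srv, paste0(names(endpoint_game)[endpoint_game == game],
                          "/putInitialLevel"),
              list(participant_id = participant_id,
                   pretest = unclass(pretest)), res)
  res
}

#' Report an attempt and receive the next level (service endpoint)
#'
#' In-process form of `<game>/putNextLevel`. For a solved level the decision
#' compares the measured time t_m against the band `t_p +/- c * sigma`; an
#' unsolved (timed out) level forces t_m to the per-game cap and the decision
#' to -1. The attempt enters the pooled store feeding the per-level sigma and
#' later refits.
#'
#' @param srv An `adaptive_service`.
#' @param game `"match3"` or `"numberlink"`.
#' @param participant_id Participant identifier.
#' @param attempt List with `level_index`, `solving_time_s`, `solved`, and
#'   optionally `session_index` (default 1) and `timestamp`.
#' @param cap_s Per-game daily cap, seconds; substituted for t_m on timeouts.
#' @return List with `decision` (-1/0/+1), `next_level_index`, `t_p`, `sigma`.
#' @export
put_next_level <- function(srv, game = c("match3", "numberlink"),
                           participant_id, attempt, cap_s = 600) {
  stopifnot(inherits(srv, "adaptive_service"))
  game <- match.arg(game)
  ladder <- srv$ladders[[game]]
  level <- ladder_level(ladder, attempt$level_index)
  session_index <- attempt$session_index %||% 1L
  solved <- isTRUE(attempt$solved)
  t_m <- if (solved) attempt$solving_time_s else cap_s
  stop_if_not_scalar_number(t_m, "solving_time_s")
  if (t_m <= 0) stop("solving_time_s must be positive")

  t_p <- service_predict(srv, game, participant_id, level, session_index)
  game_attempts <- srv$attempts[srv$attempts$game == game, , drop = FALSE]
  sigma <- level_sd(game_attempts, level, srv$config, t_p = t_p)
  decision <- if (solved) {
    decide_next_level(t_m, t_p, sigma, srv$config$c)
  } else {
    -1L
  }
  nxt <- next_level(ladder, level, decision)

  srv$attempts <- rbind(srv$attempts, data.frame(
    participant_id = participant_id, game = game, level_index = level$index,
    board_size = level$board_size, num_objects = level$num_objects,
    t_m = t_m, solved = solved, session_index = as.integer(session_index),
    timestamp = attempt$timestamp %||% NA_character_,
    stringsAsFactors = FALSE))
  st <- participant_state(srv, participant_id)
  st$level[[game]] <- nxt$index
  st$time_sum <- st$time_sum + t_m
  st$time_n <- st$time_n + 1L
  srv$participants[[participant_id]] <- st

  res <- list(decision = decision, next_level_index = nxt$index,
              t_p = t_p, sigma = sigma)
  log_request(srv, paste0(names(endpoint_game)[endpoint_game == game],
                          "/putNextLevel"),
              list(participant_id = participant_id,
                   attempt = attempt[c("level_index", "solving_time_s", "solved")]),
              res)
  res
}

#' Current ladder position of a participant
#'
#' @param srv An `adaptive_service`.
#' @param game `"match3"` or `"numberlink"`.
#' @param participant_id Participant identifier.
#' @return Integer level index (1 before any placement).
#' @export
current_level <- function(srv, game = c("match3", "numberlink"), participant_id) {
  game <- match.arg(game)
  participant_state(srv, participant_id)$level[[game]]
}

#' Handle a JSON service request
#'
#' Dispatches the four endpoint paths (`match_three/putInitialLevel`,
#' `match_three/putNextLevel`, `number_link/putInitialLevel`,
#' `number_link/putNextLevel`) on JSON bodies matching the service contract
#' and returns a JSON response; malformed requests return an error payload
#' with a 400 status instead of raising.
#'
#' @param srv An `adaptive_service`.
#' @param endpoint Endpoint path string.
#' @param body_json JSON request body.
#' @return JSON response string.
#' @export
#' @examples
#' srv <- adaptive_service()
#' handle_request(srv, "match_three/putNextLevel",
#'   '{"participant_id":"P01","attempt":{"level_index":1,"solving_time_s":20,"solved":true}}')
handle_request <- function(srv, endpoint, body_json) {
  stopifnot(inherits(srv, "adaptive_service"))
  reply <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  refuse <- function(out) {
    log_request(srv, endpoint, body_json, out)
    reply(out)
  }
  parts <- strsplit(sub("^/", "", endpoint), "/")[[1]]
  if (length(parts) != 2 || !parts[1] %in% names(endpoint_game) ||
      !parts[2] %in% c("putInitialLevel", "putNextLevel")) {
    return(refuse(list(status = 404L, error = "unknown endpoint")))
  }
  body <- tryCatch(jsonlite::fromJSON(body_json, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(body) || is.null(body$participant_id)) {
    return(refuse(list(status = 400L, error = "malformed request body")))
  }
  game <- endpoint_game[[parts[1]]]
  out <- tryCatch({
    if (parts[2] == "putInitialLevel") {
      pt <- body$pretest
      put_initial_level(srv, game, body$participant_id,
                        pretest_scores(pt$moca, pt$tmt_a, pt$tmt_b, pt$smt))
    } else {
      put_next_level(srv, game, body$participant_id, as.list(body$attempt))
    }
  }, error = function(e) {
    out <- list(status = 400L, error = conditionMessage(e))
    log_request(srv, endpoint, body_json, out)
    out
  })
  reply(out)
}

#' Service request log
#'
#' @param srv An `adaptive_service`.
#' @return List of logged requests, one entry per request handled.
#' @export
request_log <- function(srv) {
  stopifnot(inherits(srv, "adaptive_service"))
  srv$request_log
}
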