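# Batch interface binding the modules: board generation to files, full
# intervention simulation (logs, metrics, trajectories), and the analysis
# report. Every command is reproducible from (config, seeds) alone; a thin
# Rscript wrapper over these functions ships in inst/scripts/puzzlecli.R.

#' Build and validate a run configuration
#'
#' @param ... Overrides for the defaults: `n_players`, `weeks`,
#'   `sessions_per_week`, `per_game_cap_s`, `daily_cap_s`, `c`, `sigma_floor`,
#'   `min_attempts_for_sigma`, `s_range`, `g_range`, `seed`, `out_dir`.
#' @param file Optional path to a JSON file with the same fields; explicit
#'   `...` arguments win.
#' @return A validated `run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(n_players = 12L, weeks = 8L, sessions_per_week = 3L,
              per_game_cap_s = 600, daily_cap_s = 1200,
              c = 0.5, sigma_floor = 2, min_attempts_for_sigma = 3L,
              s_range = 4:8, g_range = 4:8, seed = 1L, out_dir = ".")
  if (!is.null(file)) {
    from_file <- jsonlite::fromJSON(file)
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  # validate against module preconditions before any run
  adaptive_config(cfg$c, cfg$sigma_floor, cfg$min_attempts_for_sigma)
  intervention_schedule(cfg$weeks, cfg$sessions_per_week,
                        cfg$per_game_cap_s, cfg$daily_cap_s)
  build_ladder("match3", cfg$s_range, cfg$g_range)
  if (cfg$n_players < 1) stop("n_players must be at least 1")
  structure(cfg, class = "run_config")
}

#' Generate a puzzle to a file
#'
#' Writes a serialized board: a matchless match-3 grid (integer codes) or a
#' numberlink puzzle (letters/dots). Identical (game, level, seed) always
#' produce identical bytes.
#'
#' @param game `"match3"` or `"numberlink"`.
#' @param board_size,num_objects Level parameters (4..8).
#' @param seed Integer seed.
#' @param out Output file path.
#' @return `out`, invisibly.
#' @export
cli_generate <- function(game = c("match3", "numberlink"), board_size,
                         num_objects, seed, out) {
  game <- match.arg(game)
  level <- difficulty_level(board_size, num_objects)
  text <- if (game == "match3") {
    format_grid(generate_board(level, seed))
  } else {
    format_puzzle(generate_puzzle(level, seed)$puzzle)
  }
  writeLines(sub("\n$", "", text), out)
  invisible(out)
}

#' Simulate a full multi-player intervention
#'
#' Draws `n_players` profiles from the simulator priors, pre-trains the
#' adaptive service on a synthetic pooled training set, plays every player
#' through the schedule with nightly refits, and writes the session log
#' (JSONL), the per-participant metrics (CSV) and the per-session level
#' trajectories (CSV) under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return List with `log`, `metrics`, `trajectories` and the file `paths`.
#' @export
cli_simulate <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  schedule <- intervention_schedule(config$weeks, config$sessions_per_week,
                                    config$per_game_cap_s, config$daily_cap_s)
  acfg <- adaptive_config(config$c, config$sigma_floor,
                          config$min_attempts_for_sigma)
  training <- generate_training_dataset(config$n_players, schedule,
                                        seed = derive_seed(config$seed, 1),
                                        config = acfg)
  profiles <- draw_player_profiles(config$n_players,
                                   seed = derive_seed(config$seed, 2))
  logs <- list()
  for (i in seq_len(config$n_players)) {
    srv <- adaptive_service(acfg, training = training,
                            s_range = config$s_range, g_range = config$g_range)
    logs[[i]] <- simulate_intervention(profiles[[i]], schedule, srv,
                                       participant_id = sprintf("S%02d", i))
  }
  log <- do.call(rbind, logs)
  metrics <- performance_summary(log)
  traj <- level_trajectories(log)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(log = file.path(config$out_dir, "sessions.jsonl"),
                metrics = file.path(config$out_dir, "metrics.csv"),
                trajectories = file.path(config$out_dir, "trajectories.csv"))
  write_session_log(log, paths$log)
  write_metrics_csv(metrics, paths$metrics)
  utils::write.csv(traj, paths$trajectories, row.names = FALSE)
  list(log = log, metrics = metrics, trajectories = traj, paths = paths)
}

#' Per-session difficulty-level trajectories
#'
#' The level index reached by each participant in each game at the end of
#' every session — the data behind a level-progress plot over the
#' intervention.
#'
#' @param log Session log data frame.
#' @return Data frame with `participant_id`, `game`, `session_index`,
#'   `level_index` (last level played in that session).
#' @export
level_trajectories <- function(log) {
  rows <- log_play_rows(log)
  agg <- stats::aggregate(level_index ~ participant_id + game + session_index,
                          data = rows, FUN = function(v) v[length(v)])
  agg[order(agg$participant_id, agg$game, agg$session_index), , drop = FALSE]
}

#' Analysis report from fixtures or a session log
#'
#' Fixtures mode recomputes the pretest summary block and the questionnaire
#' subscale report from the embedded tables; log mode computes the
#' per-participant performance summaries from a JSONL session log.
#'
#' @param input `"fixtures"` or a path to a JSONL session log.
#' @param out Optional directory; when given, the report tables are written
#'   there as CSV.
#' @return List of report data frames.
#' @export
cli_analyze <- function(input = "fixtures", out = NULL) {
  if (identical(input, "fixtures")) {
    fx <- load_fixtures()
    report <- list(pretest = pretest_summary(fx$participants),
                   subscales = subscale_report(fx))
  } else {
    if (!file.exists(input)) stop("usage: input must be 'fixtures' or a session log path")
    log <- read_session_log(input)
    report <- list(performance = performance_summary(log),
                   trajectories = level_trajectories(log))
  }
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(report)) {
      utils::write.csv(report[[nm]], file.path(out, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  report
}
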