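test_that("cli_generate writes deterministic, re-parseable boards", {
  out1 <- tempfile(fileext = ".txt"); out2 <- tempfile(fileext = ".txt")
  cli_generate("numberlink", 5, 5, seed = 3, out = out1)
  cli_generate("numberlink", 5, 5, seed = 3, out = out2)
  expect_identical(readLines(out1), readLines(out2))
  pz <- parse_puzzle(paste(readLines(out1), collapse = "\n"))
  expect_equal(pz$size, 5)
  expect_length(pz$pairs, 5)

  out3 <- tempfile(fileext = ".txt")
  cli_generate("match3", 4, 4, seed = 1, out = out3)
  g <- parse_grid(paste(readLines(out3), collapse = "\n"), 4)
  expect_equal(nrow(find_matches(g)), 0)
  expect_error(cli_generate("match3", 9, 4, seed = 1, out = tempfile()), "\\[4, 8\\]")
})

test_that("run_config validates against module preconditions", {
  cfg <- run_config(n_players = 2, weeks = 1)
  expect_s3_class(cfg, "run_config")
  expect_error(run_config(c = 1.5), "between 0 and 1")
  expect_error(run_config(sessions_per_week = 2), "at least 3")
  expect_error(run_config(n_players = 0), "at least 1")
  path <- tempfile(fileext = ".json")
  writeLines('{"n_players": 3, "seed": 9}', path)
  cfg2 <- run_config(file = path)
  expect_equal(cfg2$n_players, 3)
  expect_equal(cfg2$seed, 9)
})

test_that("cli_simulate emits one trajectory per player and reproducible CSVs", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- run_config(n_players = 3, weeks = 1, seed = 5, out_dir = dir1)
  res <- cli_simulate(cfg)
  expect_equal(length(unique(res$trajectories$participant_id)), 3)
  expect_equal(nrow(res$metrics), 3 * 2)
  expect_true(file.exists(res$paths$log))
  res2 <- cli_simulate(run_config(n_players = 3, weeks = 1, seed = 5, out_dir = dir2))
  expect_identical(readLines(res$paths$metrics), readLines(res2$paths$metrics))
  expect_identical(readLines(res$paths$log), readLines(res2$paths$log))
})

test_that("cli_analyze covers fixtures mode and log mode", {
  rep_fx <- cli_analyze("fixtures")
  expect_equal(rep_fx$pretest$mean_2dp[rep_fx$pretest$measure == "moca"], 27.58)
  expect_true("subscales" %in% names(rep_fx))

  sched <- intervention_schedule(weeks = 1, sessions_per_week = 3)
  log <- simulate_intervention(player_profile(noise_sd = 0.2, seed = 3), sched,
                               adaptive_service(), "P01", refit = "none")
  path <- tempfile(fileext = ".jsonl")
  write_session_log(log, path)
  rep_log <- cli_analyze(path)
  expect_equal(nrow(rep_log$performance), 2)
  expect_error(cli_analyze("no/such/file.jsonl"), "usage")
})

test_that("the JSON service contract handles the four endpoints and logs requests", {
  srv <- adaptive_service()
  fx <- load_fixtures()$participants
  med <- '{"participant_id":"P01","pretest":{"moca":28,"tmt_a":30,"tmt_b":70,"smt":15}}'
  res <- jsonlite::fromJSON(handle_request(srv, "match_three/putInitialLevel", med))
  expect_true(res$level_index >= 1 && res$level_index <= 25)
  res_nl <- jsonlite::fromJSON(handle_request(srv, "number_link/putInitialLevel", med))
  expect_true(res_nl$level_index >= 1)

  # t_m equal to the bootstrap prediction at level 1 stays (band center)
  body <- '{"participant_id":"P01","attempt":{"level_index":1,"solving_time_s":20,"solved":true}}'
  res2 <- jsonlite::fromJSON(handle_request(srv, "match_three/putNextLevel", body))
  expect_equal(res2$decision, 0)
  expect_equal(res2$next_level_index, 1)

  bad <- jsonlite::fromJSON(handle_request(srv, "match_three/putNextLevel", "{not json"))
  expect_equal(bad$status, 400)
  missing <- jsonlite::fromJSON(handle_request(
    srv, "match_three/putNextLevel",
    '{"participant_id":"P01","attempt":{"level_index":99,"solving_time_s":20,"solved":true}}'))
  expect_equal(missing$status, 400)
  unknown <- jsonlite::fromJSON(handle_request(srv, "nope/putNextLevel", body))
  expect_equal(unknown$status, 404)

  # every request is logged, including refused ones
  expect_equal(length(request_log(srv)), 6)
})
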