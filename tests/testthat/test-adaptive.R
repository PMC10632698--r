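test_that("the full ladder has 25 levels in (size, objects) lexicographic order", {
  lad <- build_ladder("match3")
  expect_length(lad$levels, 25)
  expect_equal(vapply(lad$levels, `[[`, integer(1), "index"), 1:25)
  # index = (s - 4) * 5 + (g - 4) + 1
  for (lvl in lad$levels) {
    expect_equal(lvl$index, (lvl$board_size - 4) * 5 + (lvl$num_objects - 4) + 1)
  }
  # (4, 8) precedes (5, 4)
  i48 <- Find(function(l) l$board_size == 4 && l$num_objects == 8, lad$levels)$index
  i54 <- Find(function(l) l$board_size == 5 && l$num_objects == 4, lad$levels)$index
  expect_lt(i48, i54)

  single <- build_ladder("numberlink", s_range = 4, g_range = 4)
  expect_length(single$levels, 1)
  expect_equal(single$levels[[1]]$index, 1)
  expect_error(build_ladder("match3", s_range = integer()), "empty")
})

test_that("next_level shifts by the decision and clamps at the ladder ends", {
  lad <- build_ladder("match3")
  expect_equal(next_level(lad, ladder_level(lad, 1), -1)$index, 1)
  expect_equal(next_level(lad, ladder_level(lad, 25), 1)$index, 25)
  expect_equal(next_level(lad, ladder_level(lad, 7), 1)$index, 8)
  expect_equal(next_level(lad, ladder_level(lad, 7), 0)$index, 7)
})

test_that("the level decision follows the piecewise threshold rule with strict boundaries", {
  expect_equal(decide_next_level(10, 10, 2, 0.5), 0)
  expect_equal(decide_next_level(11, 10, 2, 0.5), 0)      # boundary t_p + c*sigma
  expect_equal(decide_next_level(11.01, 10, 2, 0.5), -1)
  expect_equal(decide_next_level(9, 10, 2, 0.5), 0)       # boundary t_p - c*sigma
  expect_equal(decide_next_level(8.9, 10, 2, 0.5), 1)
})

test_that("decision symmetry and band-width monotonicity hold", {
  set.seed(1)
  for (rep in 1:200) {
    sigma <- runif(1, 0, 30)
    cc <- runif(1, 0.05, 0.95)
    delta <- cc * sigma + runif(1, 0.001, 50)
    t_p <- delta + runif(1, 1, 100)  # keep t_m = t_p - delta positive
    expect_equal(decide_next_level(t_p - delta, t_p, sigma, cc), 1)
    expect_equal(decide_next_level(t_p + delta, t_p, sigma, cc), -1)
    # widening the band never converts a 0 into +/-1
    t_m <- runif(1, 1, 300)
    d1 <- decide_next_level(t_m, t_p, sigma, cc)
    c2 <- runif(1, cc, 0.99)
    if (d1 == 0) expect_equal(decide_next_level(t_m, t_p, sigma, c2), 0)
  }
})

test_that("adjusted R-squared matches its closed form and rejects tiny n", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_equal(adjusted_r2(0, 11, 1), -1 / 9)
  expect_equal(adjusted_r2(0.8, 21, 4), 0.75)
  expect_error(adjusted_r2(0.5, 5, 4), "n > p")
})

test_that("per-level SD is the sample SD with a floor-based fallback", {
  att <- data.frame(level_index = c(3, 3, 3, 5), t_m = c(10, 12, 14, 99))
  cfg <- adaptive_config()
  expect_equal(level_sd(att, 3, cfg), 2)
  # single attempt at level 5: fallback max(sigma_floor, 0.2 * t_p)
  expect_equal(level_sd(att, 5, cfg, t_p = 50), 10)
  expect_equal(level_sd(att, 5, cfg, t_p = 5), 2)
  expect_equal(level_sd(att, 9, cfg), 2)
  set.seed(2)
  for (rep in 1:20) {
    x <- rlnorm(sample(3:40, 1), 3, 0.4)
    att <- data.frame(level_index = rep(1, length(x)), t_m = x)
    expect_equal(level_sd(att, 1, cfg), two_pass_sd(x), tolerance = 1e-12)
  }
})

test_that("noiseless linear attempts are recovered exactly and the linear candidate wins", {
  att <- linear_attempts()
  model <- fit_time_model(att)
  expect_equal(model$type, "linear")
  lin <- model$meta[model$meta$candidate == "linear", ]
  expect_equal(lin$adj_r2, 1, tolerance = 1e-10)
  # adding more candidate families never changes the selection on noiseless data
  model2 <- fit_time_model(att, candidates = c("linear", "knn", "committee", "knn"))
  expect_equal(model2$type, "linear")
  lad <- build_ladder("match3")
  preds <- vapply(1:10, function(i) {
    predict_time(model, ladder_level(lad, i), history = list(session_index = 1))
  }, numeric(1))
  expect_equal(preds, 20 + 15 * (1:10), tolerance = 1e-8)
  expect_true(all(diff(preds) >= 0))
  expect_warning(predict_time(model, ladder_level(lad, 20)), "extrapolat")
})

test_that("time-model preconditions reject degenerate designs", {
  att <- linear_attempts()
  expect_error(fit_time_model(att[1:10, ]), "at least 20")
  one_level <- att; one_level$level_index <- 1L
  one_level$board_size <- 4L; one_level$num_objects <- 4L
  expect_error(fit_time_model(one_level), "single level")
})

test_that("prediction depends on the history summary, not the attempt ordering", {
  att <- linear_attempts()
  model <- fit_time_model(att)
  lad <- build_ladder("match3")
  h <- list(session_index = 3, run_mean = 80)
  expect_equal(predict_time(model, ladder_level(lad, 4), h),
               predict_time(model, ladder_level(lad, 4), h[c(2, 1)]))
})

test_that("initial level placement is monotone in the pretest composite", {
  lad <- build_ladder("match3")
  fx <- load_fixtures()$participants
  ref <- lapply(seq_len(nrow(fx)), function(i) {
    pretest_scores(fx$moca[i], fx$tmt_a_s[i], fx$tmt_b_s[i], fx$smt_s[i])
  })
  # the median-ranked reference composite maps to the middle quintile's start
  mu <- c(tmt_a = mean(fx$tmt_a_s), smt = mean(fx$smt_s), moca = mean(fx$moca))
  sdv <- c(tmt_a = sd(fx$tmt_a_s), smt = sd(fx$smt_s), moca = sd(fx$moca))
  ref_comp <- vapply(ref, function(p) {
    mean(c(-(p$tmt_a - mu["tmt_a"]) / sdv["tmt_a"],
           -(p$smt - mu["smt"]) / sdv["smt"],
           (p$moca - mu["moca"]) / sdv["moca"]))
  }, numeric(1))
  med <- ref[[which(rank(ref_comp) == 6)]]
  expect_equal(assign_initial_level(med, lad, ref)$index, 11)
  best <- pretest_scores(30, min(fx$tmt_a_s) - 1, min(fx$tmt_b_s), min(fx$smt_s) - 1)
  expect_equal(assign_initial_level(best, lad, ref)$index, 21)
  worst <- pretest_scores(min(fx$moca) - 2, max(fx$tmt_a_s) + 10,
                          max(fx$tmt_b_s), max(fx$smt_s) + 10)
  expect_equal(assign_initial_level(worst, lad, ref)$index, 1)

  # rank order of composites is preserved (weakly) in level order
  set.seed(3)
  pts <- replicate(100, pretest_scores(sample(20:30, 1), runif(1, 15, 60),
                                       runif(1, 40, 280), runif(1, 8, 40)),
                   simplify = FALSE)
  mu <- c(tmt_a = mean(fx$tmt_a_s), smt = mean(fx$smt_s), moca = mean(fx$moca))
  sdv <- c(tmt_a = sd(fx$tmt_a_s), smt = sd(fx$smt_s), moca = sd(fx$moca))
  comp <- vapply(pts, function(p) {
    mean(c(-(p$tmt_a - mu["tmt_a"]) / sdv["tmt_a"],
           -(p$smt - mu["smt"]) / sdv["smt"],
           (p$moca - mu["moca"]) / sdv["moca"]))
  }, numeric(1))
  idx <- vapply(pts, function(p) assign_initial_level(p, lad, ref)$index, numeric(1))
  ord <- order(comp)
  expect_true(all(diff(idx[ord]) >= 0))
  expect_true(all(idx >= 1 & idx <= 25))
})
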