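test_that("fixtures load with the printed values and checksums", {
  fx <- load_fixtures()
  expect_equal(nrow(fx$participants), 12)
  r01 <- fx$participants[fx$participants$id == "01", ]
  expect_equal(c(r01$age, r01$moca, r01$tmt_a_s, r01$tmt_b_s, r01$smt_s),
               c(75, 26, 38, 119, 27))
  expect_equal(sum(fx$participants$group == "control"), 7)
  expect_equal(sum(fx$participants$group == "experimental"), 5)
  expect_equal(nrow(fx$imi), 12)
  expect_equal(nrow(fx$tlx), 12)
  expect_false("09" %in% fx$participants$id)
})

test_that("mean (SD) summaries use the sample SD", {
  s <- summarize_scores(c(5, 5, 5))
  expect_equal(c(s$mean, s$sd), c(5, 0))
  fx <- load_fixtures()
  age <- summarize_scores(fx$participants$age)
  expect_equal(round(age$mean, 2), 58.92)
  expect_equal(round(age$sd, 2), 10.28)
  expect_error(summarize_scores(3), "at least 2")
})

test_that("Shapiro-Wilk matches the AS R94 reference and behaves at the extremes", {
  # near-normal quantile sample: W close to 1
  x <- qnorm((1:12 - 0.5) / 12)
  expect_gt(shapiro_wilk(x)$W, 0.95)
  # heavily bimodal: far below the 5% critical region for n = 12
  bim <- c(rep(0, 6), rep(100, 6))
  res_bim <- shapiro_wilk(bim)
  expect_lt(res_bim$W, 0.8)
  expect_lt(res_bim$p, 0.001)
  expect_error(shapiro_wilk(rep(1, 12)), "constant")
  expect_error(shapiro_wilk(1:60), "n <= 50")
  set.seed(5)
  for (rep in 1:20) {
    y <- rnorm(sample(12:50, 1))
    got <- shapiro_wilk(y)
    ref <- shapiro_r94(y)
    expect_equal(got$W, ref$W, tolerance = 1e-6)
    expect_equal(got$p, ref$p, tolerance = 1e-5)
  }
})

test_that("paired t matches its closed form and rejects zero-variance differences", {
  expect_error(paired_t(1:5, 1:5), "zero variance")
  expect_error(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
  # hand-computable example, n = 4: d = (2, -1, 3, 2), mean 1.5, sd ~ 1.7321
  pre <- c(12, 9, 14, 11); post <- c(10, 10, 11, 9)
  res <- paired_t(pre, post)
  d <- pre - post
  expect_equal(res$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(abs(res$t), 3, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches the closed form and the aov oracle", {
  # all waves identical per participant -> F = 0
  res <- rm_anova(cbind(1:6, 1:6, 1:6))
  expect_equal(res$F, 0)

  # hand-computed 3x3 example: SS_wave / SS_error from first principles
  m2 <- rbind(c(10, 12, 9), c(14, 11, 13), c(9, 10, 14))
  grand <- mean(m2)
  ss_wave <- 3 * sum((colMeans(m2) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m2) - grand)^2)
  ss_err <- sum((m2 - grand)^2) - ss_wave - ss_subj
  res2 <- rm_anova(m2)
  expect_equal(res2$F, (ss_wave / 2) / (ss_err / 4), tolerance = 1e-12)
  expect_equal(res2$df1, 2)
  expect_equal(res2$df2, 4)

  # df for the three-wave, n = 12 design
  set.seed(6)
  m12 <- matrix(rnorm(36, 50, 5), 12, 3)
  res12 <- rm_anova(m12)
  expect_equal(c(res12$df1, res12$df2), c(2, 22))
  ref <- aov_rm_f(m12)
  expect_equal(res12$F, ref$F, tolerance = 1e-8)
  expect_equal(res12$p, ref$p, tolerance = 1e-8)

  # Greenhouse-Geisser epsilon: 1 under two waves, <= 1 and F unchanged otherwise
  gg <- rm_anova(m12, correction = "greenhouse-geisser")
  expect_equal(gg$F, res12$F)
  expect_lte(gg$epsilon, 1 + 1e-12)
  expect_gte(gg$epsilon, 1 / 2)  # lower bound 1/(k-1)
  expect_error(rm_anova(cbind(c(1, NA, 3), 1:3, 1:3)), "missing")
})

test_that("Pearson correlation matches the covariance closed form", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  # orthogonal pair by construction
  a <- c(-1, 1, -1, 1); b <- c(1, 1, -1, -1)
  expect_equal(pearson_r(a, b)$r, 0)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  set.seed(7)
  for (rep in 1:20) {
    u <- rnorm(sample(5:30, 1)); v <- rnorm(length(u), u, 2)
    got <- pearson_r(u, v)
    r_ref <- sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
    t_ref <- r_ref * sqrt((length(u) - 2) / (1 - r_ref^2))
    expect_equal(got$r, r_ref, tolerance = 1e-10)
    expect_equal(got$p, 2 * pt(abs(t_ref), length(u) - 2, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("questionnaire subscale orderings match the reported pattern", {
  rep_tab <- subscale_report(load_fixtures())
  imi <- rep_tab[rep_tab$instrument == "imi", ]
  expect_equal(imi$subscale[which.max(imi$total)], "interest_enjoyment")
  expect_equal(imi$subscale[which.min(imi$total)], "value_usefulness")
  tlx <- rep_tab[rep_tab$instrument == "tlx", ]
  expect_equal(tlx$subscale[which.min(tlx$total)], "physical_demand")
  expect_equal(tlx$rank[tlx$subscale == "physical_demand"], 6)
})

test_that("the pretest summary reproduces the printed report cells", {
  ps <- pretest_summary()
  expect_equal(ps$mean_2dp, c(58.92, 27.58, 32.25, 91.83, 19.17))
  expect_equal(ps$sd_2dp[ps$measure == "age"], 10.28)
})
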