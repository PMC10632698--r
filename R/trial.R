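# Crossover-trial statistics. The participant characteristics (age, MoCA,
# TMT-A/B, SMT), motivation (IMI) and workload (NASA-TLX) tables of the
# N = 12 pilot are shipped as CSV fixtures (participant 09 was excluded from
# the trial for incomplete measurements and is not part of the tables). The
# module reproduces the pretest summary cells and the questionnaire subscale
# orderings, and provides the test statistics used in the analysis.

# Column sums of the shipped fixtures; a mismatch signals transcription
# corruption.
fixture_checksums <- list(
  participants = c(age = 707, moca = 331, tmt_a_s = 387, tmt_b_s = 1102,
                   smt_s = 230),
  imi = c(competence_effort = 148, interest_enjoyment = 472,
          value_usefulness = 90, pressure_tension = 225),
  tlx = c(mental_demand = 99, physical_demand = 16, temporal_demand = 69,
          performance = 61, effort = 63, frustration = 37)
)

#' Load the embedded trial fixtures
#'
#' Reads the participant, IMI and NASA-TLX tables shipped with the package and
#' verifies their column checksums.
#'
#' @return List with data frames `participants` (12 rows: id, group, age,
#'   gender, handedness, moca, tmt_a_s, tmt_b_s, smt_s), `imi` (4 subscales)
#'   and `tlx` (6 subscales).
#' @export
load_fixtures <- function() {
  read_one <- function(name) {
    path <- system.file("extdata", paste0(name, ".csv"), package = "puzzletrain")
    if (path == "") stop("fixture file missing: ", name)
    utils::read.csv(path, colClasses = c(id = "character"))
  }
  out <- list(participants = read_one("participants"), imi = read_one("imi"),
              tlx = read_one("tlx"))
  for (tab in names(fixture_checksums)) {
    sums <- colSums(out[[tab]][names(fixture_checksums[[tab]])])
    if (!isTRUE(all.equal(unname(sums), unname(fixture_checksums[[tab]])))) {
      stop("fixture checksum mismatch in ", tab, ": transcription corruption")
    }
  }
  if (nrow(out$participants) != 12) stop("expected 12 participant records")
  out
}

#' Mean and sample SD
#'
#' The "mean (SD)" summary used throughout the trial report: arithmetic mean
#' and sample SD (n - 1 denominator). Rounding happens only at the report
#' layer.
#'
#' @param values Numeric vector (n >= 2 for the SD).
#' @return List with `mean` and `sd`.
#' @export
#' @examples
#' summarize_scores(load_fixtures()$participants$age)
summarize_scores <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values for a mean (SD) summary")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 <= n <= 50, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 50) stop("Shapiro-Wilk requires 3 <= n <= 50")
  if (stats::sd(values) == 0) stop("W undefined for a constant sample")
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Paired t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = pre - post`, `df = n - 1`,
#' two-sided p.
#'
#' @param pre,post Paired numeric vectors of equal length (n >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 2) stop("need at least 2 pairs")
  d <- pre - post
  if (stats::sd(d) == 0) stop("zero variance of differences: t undefined")
  res <- stats::t.test(pre, post, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter), p = res$p.value)
}

#' One-way repeated-measures ANOVA
#'
#' Univariate within-subject F for a complete participants x waves matrix,
#' computed from the sums of squares: `F = MS_wave / MS_error` with
#' `df1 = k - 1` and `df2 = (k - 1)(n - 1)` (for the three measurement waves
#' and n = 12, df1 = 2 and df2 = 22). By default no sphericity correction is
#' applied; `correction = "greenhouse-geisser"` scales both df by the
#' Greenhouse-Geisser epsilon.
#'
#' @param mat Numeric matrix, one row per participant, one column per wave
#'   (no missing cells, >= 3 participants, >= 2 waves).
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return List with `F`, `df1`, `df2`, `p` (and `epsilon` when corrected).
#' @export
rm_anova <- function(mat, correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells: complete cases required")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3) stop("need at least 3 participants")
  if (k < 2) stop("need at least 2 waves")
  grand <- mean(mat)
  ss_total <- sum((mat - grand)^2)
  ss_subject <- k * sum((rowMeans(mat) - grand)^2)
  ss_wave <- n * sum((colMeans(mat) - grand)^2)
  ss_error <- ss_total - ss_subject - ss_wave
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_error <- ss_error / df2
  f <- if (ss_wave == 0) 0 else (ss_wave / df1) / ms_error
  if (correction == "none") {
    return(list(F = f, df1 = df1, df2 = df2,
                p = stats::pf(f, df1, df2, lower.tail = FALSE)))
  }
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  s <- stats::cov(mat)
  dc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) + mean(s)
  eps <- sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
  list(F = f, df1 = df1 * eps, df2 = df2 * eps, epsilon = eps,
       p = stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return List with `r` and `p` (t transform, df = n - 2).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p = res$p.value)
}

#' Questionnaire subscale totals and ranks
#'
#' Sums each IMI and NASA-TLX subscale over the 12 participants and ranks the
#' subscales within each instrument (rank 1 = highest total).
#'
#' @param fixtures Fixture list from [load_fixtures()].
#' @return Data frame with columns `instrument`, `subscale`, `total`, `rank`.
#' @export
#' @examples
#' rep <- subscale_report(load_fixtures())
#' subset(rep, instrument == "imi" & rank == 1)$subscale # interest_enjoyment
subscale_report <- function(fixtures = load_fixtures()) {
  one <- function(tab, instrument) {
    totals <- colSums(tab[setdiff(names(tab), "id")])
    data.frame(instrument = instrument, subscale = names(totals),
               total = unname(totals),
               rank = rank(-unname(totals), ties.method = "min"),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(one(fixtures$imi, "imi"), one(fixtures$tlx, "tlx"))
}

#' Pretest summary block
#'
#' The "mean (SD)" pretest cells recomputed from the participant table: age,
#' MoCA, TMT-A, TMT-B and SMT over the 12 participants.
#'
#' @param participants Participant data frame (defaults to the fixtures).
#' @return Data frame with columns `measure`, `mean`, `sd` and the rounded
#'   2-decimal report columns `mean_2dp`, `sd_2dp`.
#' @export
pretest_summary <- function(participants = load_fixtures()$participants) {
  cols <- c(age = "age", moca = "moca", tmt_a = "tmt_a_s", tmt_b = "tmt_b_s",
            smt = "smt_s")
  out <- lapply(names(cols), function(m) {
    s <- summarize_scores(participants[[cols[[m]]]])
    data.frame(measure = m, mean = s$mean, sd = s$sd,
               mean_2dp = round(s$mean, 2), sd_2dp = round(s$sd, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
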