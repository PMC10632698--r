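# Adaptive difficulty: the data-driven service that keeps the puzzle level
# matched to the player. A fitted regressor predicts the solving time t_p for
# the level just played; the measured time t_m is compared against a band of
# half-width c * sigma around t_p, where sigma is the SD of all games played
# at that level in the data set; the level predictor returns -1 (retreat),
# 0 (stay) or +1 (advance).

#' Adaptive service configuration
#'
#' @param c Threshold constant, dimensionless, strictly between 0 and 1.
#'   Scales the decision band half-width `c * sigma`.
#' @param sigma_floor Lower bound for the fallback band width, seconds.
#' @param min_attempts_for_sigma Minimum attempts at a level before the sample
#'   SD is trusted; below it the fallback `max(sigma_floor, 0.2 * t_p)` is used.
#' @return An `adaptive_config` object.
#' @export
adaptive_config <- function(c = 0.5, sigma_floor = 2, min_attempts_for_sigma = 3L) {
  stop_if_not_scalar_number(c, "c")
  if (c <= 0 || c >= 1) stop("c must lie strictly between 0 and 1")
  if (sigma_floor < 0) stop("sigma_floor must be nonnegative")
  structure(list(c = c, sigma_floor = sigma_floor,
                 min_attempts_for_sigma = as.integer(min_attempts_for_sigma)),
            class = "adaptive_config")
}

#' Pretest scores used for initial level placement
#'
#' @param moca Montreal Cognitive Assessment score (0-30).
#' @param tmt_a,tmt_b Trail Making Test part A / B completion times, seconds.
#' @param smt Snellgrove Maze Task completion time, seconds.
#' @return A `pretest_scores` object.
#' @export
pretest_scores <- function(moca, tmt_a, tmt_b, smt) {
  for (nm in c("moca", "tmt_a", "tmt_b", "smt")) {
    v <- get(nm)
    stop_if_not_scalar_number(v, nm)
    if (v <= 0) stop(sprintf("`%s` must be positive", nm))
  }
  if (moca > 30) stop("moca cannot exceed 30")
  structure(list(moca = moca, tmt_a = tmt_a, tmt_b = tmt_b, smt = smt),
            class = "pretest_scores")
}

#' Level decision from measured and predicted solving time
#'
#' The piecewise rule: retreat one level (-1) when `t_m > t_p + c * sigma`,
#' advance one level (+1) when `t_m < t_p - c * sigma`, stay (0) otherwise.
#' Inequalities are strict, so a time exactly on a band edge stays.
#'
#' @param t_m Measured solving time, seconds (> 0).
#' @param t_p Predicted solving time, seconds (> 0).
#' @param sigma SD of solving times at the level, seconds (>= 0).
#' @param c Threshold constant in (0, 1).
#' @return -1, 0 or +1 (integer).
#' @export
#' @examples
#' decide_next_level(t_m = 8.9, t_p = 10, sigma = 2, c = 0.5) # +1
decide_next_level <- function(t_m, t_p, sigma, c = 0.5) {
  stop_if_not_scalar_number(t_m, "t_m"); stop_if_not_scalar_number(t_p, "t_p")
  stop_if_not_scalar_number(sigma, "sigma"); stop_if_not_scalar_number(c, "c")
  if (t_m <= 0 || t_p <= 0) stop("solving times must be positive")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (c <= 0 || c >= 1) stop("c must lie strictly between 0 and 1")
  if (t_m > t_p + c * sigma) return(-1L)
  if (t_m < t_p - c * sigma) return(1L)
  0L
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`: the R-squared penalized for model
#' dimensionality, used to select the time-prediction regressor on its
#' training data.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number of predictors.
#' @return Adjusted R-squared (can be negative).
#' @export
#' @examples
#' adjusted_r2(0.8, 21, 4) # 0.75
adjusted_r2 <- function(r2, n, p) {
  stop_if_not_scalar_number(r2, "r2")
  if (n <= p + 1) stop("adjusted R-squared requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Per-level solving-time SD
#'
#' Sample SD (n-1 denominator) of the measured times of all games played at
#' the given level in `attempts`. With fewer than
#' `config$min_attempts_for_sigma` attempts the fallback
#' `max(sigma_floor, 0.2 * t_p)` is returned (just `sigma_floor` when no
#' prediction is supplied), avoiding a zero-width band that would thrash the
#' level.
#'
#' @param attempts Attempt data frame (see [attempt_records()]).
#' @param level A `difficulty_level` or integer level index.
#' @param config An [adaptive_config()].
#' @param t_p Optional predicted time used by the fallback.
#' @return SD in seconds.
#' @export
level_sd <- function(attempts, level, config = adaptive_config(), t_p = NA_real_) {
  idx <- if (inherits(level, "difficulty_level")) level$index else as.integer(level)
  times <- if (is.null(attempts) || nrow(attempts) == 0) {
    numeric()
  } else {
    attempts$t_m[attempts$level_index == idx]
  }
  if (length(times) >= config$min_attempts_for_sigma) {
    return(stats::sd(times))
  }
  if (is.na(t_p)) config$sigma_floor else max(config$sigma_floor, 0.2 * t_p)
}

#' Validate and normalize a table of attempt records
#'
#' The canonical tabular form of gameplay attempts used for model fitting:
#' one row per completed or attempted level.
#'
#' @param df Data frame with columns `participant_id`, `game`
#'   ("match3"/"numberlink"), `level_index`, `board_size`, `num_objects`,
#'   `t_m` (seconds, > 0), `solved` (logical), `session_index` (>= 1) and
#'   optionally `timestamp`.
#' @return The validated data frame (invisibly classed `attempt_records`).
#' @export
attempt_records <- function(df) {
  need <- c("participant_id", "game", "level_index", "board_size",
            "num_objects", "t_m", "solved", "session_index")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing attempt columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$t_m <= 0)) stop("t_m must be positive")
  if (any(df$session_index < 1)) stop("session_index must be >= 1")
  if (!all(df$game %in% c("match3", "numberlink"))) stop("unknown game")
  if (!"timestamp" %in% names(df)) df$timestamp <- NA_character_
  class(df) <- c("attempt_records", class(df))
  df
}

# Feature matrix for the time model: board size, object count, ladder index,
# session index, and the participant's running mean time over earlier
# attempts (the pooled grand mean stands in before a participant's first
# attempt).
attempt_features <- function(attempts, fallback_run_mean = NULL) {
  if (is.null(fallback_run_mean)) fallback_run_mean <- mean(attempts$t_m)
  run_mean <- numeric(nrow(attempts))
  sums <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(attempts))) {
    id <- attempts$participant_id[i]
    st <- sums[[id]] %||% c(0, 0)
    run_mean[i] <- if (st[2] > 0) st[1] / st[2] else fallback_run_mean
    sums[[id]] <- st + c(attempts$t_m[i], 1)
  }
  cbind(board_size = attempts$board_size,
        num_objects = attempts$num_objects,
        level_index = attempts$level_index,
        session_index = attempts$session_index,
        run_mean = run_mean)
}

knn_predict <- function(train_x, train_y, scale_center, scale_sd, query_x, k) {
  tx <- sweep(sweep(train_x, 2, scale_center), 2, scale_sd, `/`)
  qx <- sweep(sweep(query_x, 2, scale_center), 2, scale_sd, `/`)
  apply(qx, 1, function(q) {
    d2 <- colSums((t(tx) - q)^2)
    mean(train_y[order(d2)[seq_len(k)]])
  })
}

#' Fit the solving-time predictor
#'
#' Fits every candidate regressor family on the attempt feature set (board
#' size, object count, level index, session index, participant running mean
#' time) and selects the one with the highest adjusted R-squared on the
#' training data. Candidates: `"linear"` (ordinary least squares),
#' `"knn"` (k-nearest-mean, k = 5, standardized features) and `"committee"`
#' (equal-weight average of the two, a voting-regressor analogue). Ties keep
#' the earlier candidate in the order given.
#'
#' @param attempts Attempt records (>= 20 rows spanning >= 2 levels).
#' @param candidates Character vector of candidate families to consider.
#' @param k Neighbourhood size for the k-nearest-mean candidate.
#' @return A `time_model`: the selected fit plus `meta`, a data frame of
#'   (candidate, r2, adj_r2, n, p) for every candidate.
#' @export
fit_time_model <- function(attempts,
                           candidates = c("linear", "knn", "committee"),
                           k = 5L) {
  attempts <- attempt_records(as.data.frame(attempts))
  n <- nrow(attempts)
  if (n < 20) stop("need at least 20 attempts to fit the time model")
  if (length(unique(attempts$level_index)) < 2) {
    stop("degenerate design: attempts span a single level")
  }
  if (stats::var(attempts$t_m) == 0) stop("degenerate design: zero time variance")
  y <- attempts$t_m
  x <- attempt_features(attempts)
  p <- ncol(x)
  sst <- sum((y - mean(y))^2)
  scale_center <- colMeans(x)
  scale_sd <- apply(x, 2, stats::sd)
  scale_sd[scale_sd == 0] <- 1
  k_eff <- min(as.integer(k), n)

  lin_fit <- NULL
  preds <- list()
  for (cand in candidates) {
    preds[[cand]] <- switch(
      cand,
      linear = {
        dat <- data.frame(y = y, x)
        lin_fit <- stats::lm(y ~ ., data = dat)
        as.numeric(stats::fitted(lin_fit))
      },
      knn = knn_predict(x, y, scale_center, scale_sd, x, k_eff),
      committee = {
        lp <- if (!is.null(preds[["linear"]])) preds[["linear"]] else {
          dat <- data.frame(y = y, x)
          lin_fit <- stats::lm(y ~ ., data = dat)
          as.numeric(stats::fitted(lin_fit))
        }
        kp <- preds[["knn"]] %||% knn_predict(x, y, scale_center, scale_sd, x, k_eff)
        (lp + kp) / 2
      },
      stop("unknown candidate family: ", cand)
    )
  }
  meta <- do.call(rbind, lapply(candidates, function(cand) {
    r2 <- 1 - sum((y - preds[[cand]])^2) / sst
    data.frame(candidate = cand, r2 = r2, adj_r2 = adjusted_r2(r2, n, p),
               n = n, p = p)
  }))
  selected <- meta$candidate[which.max(meta$adj_r2)]
  structure(
    list(type = selected, meta = meta, lin_fit = lin_fit,
         train_x = x, train_y = y, k = k_eff,
         scale_center = scale_center, scale_sd = scale_sd,
         fallback_run_mean = mean(y),
         level_range = range(attempts$level_index)),
    class = "time_model"
  )
}

#' @export
print.time_model <- function(x, ...) {
  cat(sprintf("<time_model> selected '%s' (n = %d)\n", x$type, x$meta$n[1]))
  print(x$meta, row.names = FALSE)
  invisible(x)
}

#' Predict the solving time for a level
#'
#' @param model A fitted [fit_time_model()] object.
#' @param level A `difficulty_level` (with ladder index).
#' @param history Summary of the participant's history:
#'   `list(session_index =, run_mean =)`; a missing `run_mean` falls back to
#'   the training grand mean.
#' @return Predicted time t_p in seconds, finite and clamped below at 1 s. A
#'   level outside the training ladder range raises an extrapolation warning.
#' @export
predict_time <- function(model, level, history = list()) {
  stopifnot(inherits(model, "time_model"), inherits(level, "difficulty_level"))
  if (is.na(level$index)) stop("level must carry a ladder index")
  if (level$index < model$level_range[1] || level$index > model$level_range[2]) {
    warning(sprintf("level index %d outside training range [%d, %d]: extrapolating",
                    level$index, model$level_range[1], model$level_range[2]))
  }
  q <- cbind(board_size = level$board_size,
             num_objects = level$num_objects,
             level_index = level$index,
             session_index = history$session_index %||% 1,
             run_mean = history$run_mean %||% model$fallback_run_mean)
  pred <- switch(
    model$type,
    linear = as.numeric(suppressWarnings(
      stats::predict(model$lin_fit, newdata = as.data.frame(q)))),
    knn = knn_predict(model$train_x, model$train_y, model$scale_center,
                      model$scale_sd, q, model$k),
    committee = {
      lp <- as.numeric(suppressWarnings(
        stats::predict(model$lin_fit, newdata = as.data.frame(q))))
      kp <- knn_predict(model$train_x, model$train_y, model$scale_center,
                        model$scale_sd, q, model$k)
      (lp + kp) / 2
    }
  )
  if (!is.finite(pred)) stop("non-finite time prediction")
  max(1, pred)
}

#' Assign the initial difficulty level from pretest scores
#'
#' The composite is the mean of the standardized triplet
#' (-TMT-A, -SMT, MoCA) against a reference population (faster trail-making
#' and maze times and higher MoCA give a higher composite). The composite's
#' empirical quantile within the reference maps to one of five starting
#' levels, the lowest index of each ladder quintile, so better pretests start
#' weakly higher and the best start at the top quintile's first level.
#'
#' @param pretest A [pretest_scores()] object.
#' @param ladder A `difficulty_ladder`.
#' @param reference List of `pretest_scores` forming the reference population;
#'   defaults to the embedded participant table.
#' @return The starting `difficulty_level`.
#' @export
assign_initial_level <- function(pretest, ladder, reference = NULL) {
  stopifnot(inherits(pretest, "pretest_scores"), inherits(ladder, "difficulty_ladder"))
  if (is.null(reference)) {
    parts <- load_fixtures()$participants
    reference <- lapply(seq_len(nrow(parts)), function(i) {
      pretest_scores(parts$moca[i], parts$tmt_a_s[i], parts$tmt_b_s[i], parts$smt_s[i])
    })
  }
  if (!length(reference)) stop("reference population must be nonempty")
  ref <- do.call(rbind, lapply(reference, function(p) {
    c(moca = p$moca, tmt_a = p$tmt_a, smt = p$smt)
  }))
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  sdv[sdv == 0] <- 1
  composite <- function(moca, tmt_a, smt) {
    mean(c(-(tmt_a - mu["tmt_a"]) / sdv["tmt_a"],
           -(smt - mu["smt"]) / sdv["smt"],
           (moca - mu["moca"]) / sdv["moca"]))
  }
  ref_comp <- apply(ref, 1, function(r) composite(r["moca"], r["tmt_a"], r["smt"]))
  x <- composite(pretest$moca, pretest$tmt_a, pretest$smt)
  f <- mean(ref_comp <= x)
  quintile <- min(5L, as.integer(floor(f * 5)) + 1L)
  n_levels <- length(ladder$levels)
  start_index <- as.integer(floor((quintile - 1L) * n_levels / 5)) + 1L
  ladder_level(ladder, start_index)
}
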