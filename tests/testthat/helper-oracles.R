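# Independent brute-force oracles used by the tests. Deliberately written
# with plain loops, separate from the package's implementations.

# All maximal runs of >= 3 equal codes, scanning every row and column cell by
# cell. Returns a data frame (orientation, row, col, length, code).
brute_runs <- function(cells) {
  out <- list()
  scan_line <- function(v, fix, orientation) {
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[j + 1] == v[i]) j <- j + 1
      if (j - i + 1 >= 3) {
        out[[length(out) + 1]] <<- if (orientation == "h") {
          data.frame(orientation = "h", row = fix, col = i,
                     length = j - i + 1, code = v[i])
        } else {
          data.frame(orientation = "v", row = i, col = fix,
                     length = j - i + 1, code = v[i])
        }
      }
      i <- j + 1
    }
  }
  for (r in seq_len(nrow(cells))) scan_line(cells[r, ], r, "h")
  for (c in seq_len(ncol(cells))) scan_line(cells[, c], c, "v")
  if (!length(out)) {
    return(data.frame(orientation = character(), row = integer(),
                      col = integer(), length = integer(), code = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$orientation, res$row, res$col), , drop = FALSE]
}

# Every adjacent swap that creates at least one run, by trying all of them.
brute_moves <- function(cells) {
  moves <- list()
  h <- nrow(cells); w <- ncol(cells)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (nb in list(c(i, j + 1), c(i + 1, j))) {
        if (nb[1] > h || nb[2] > w) next
        if (cells[i, j] == cells[nb[1], nb[2]]) next
        tmp <- cells
        tmp[i, j] <- cells[nb[1], nb[2]]
        tmp[nb[1], nb[2]] <- cells[i, j]
        if (nrow(brute_runs(tmp)) > 0) {
          moves[[length(moves) + 1]] <- list(a = c(i, j), b = nb)
        }
      }
    }
  }
  moves
}

# Two-pass sample SD.
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# OLS slope by the covariance closed form.
ols_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)

# Shapiro-Wilk W and p by the published AS R94 approximation, valid here for
# 12 <= n <= 50 (polynomial coefficients for the two largest weights and the
# lognormal null transform).
shapiro_r94 <- function(x) {
  n <- length(x)
  stopifnot(n >= 12, n <= 50)
  xs <- sort(x)
  m <- qnorm((seq_len(n) - 0.375) / (n + 0.25))
  ssq_m <- sum(m^2)
  c_vec <- m / sqrt(ssq_m)
  u <- 1 / sqrt(n)
  a_n <- c_vec[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
    4.434685 * u^4 - 2.706056 * u^5
  a_n1 <- c_vec[n - 1] + 0.042981 * u - 0.293762 * u^2 - 1.752461 * u^3 +
    5.682633 * u^4 - 3.582633 * u^5
  phi <- (ssq_m - 2 * m[n]^2 - 2 * m[n - 1]^2) / (1 - 2 * a_n^2 - 2 * a_n1^2)
  a <- m / sqrt(phi)
  a[n] <- a_n; a[1] <- -a_n
  a[n - 1] <- a_n1; a[2] <- -a_n1
  W <- sum(a * xs)^2 / sum((xs - mean(xs))^2)
  lw <- log(1 - W)
  ln <- log(n)
  mu <- 0.0038915 * ln^3 - 0.083751 * ln^2 - 0.31082 * ln - 1.5861
  sigma <- exp(0.0030302 * ln^2 - 0.082676 * ln - 0.4803)
  list(W = W, p = pnorm((lw - mu) / sigma, lower.tail = FALSE))
}

# One-way within-subject F via stats::aov with an Error stratum.
aov_rm_f <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(seq_len(n), k)),
                   wave = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ wave + Error(subject / wave), data = df)
  tab <- summary(fit)[["Error: subject:wave"]][[1]]
  list(F = tab["wave", "F value"], p = tab["wave", "Pr(>F)"])
}

# Canonical 3x3 numberlink puzzle: three pairs at the row ends; its unique
# solution is the three horizontal rows.
three_row_puzzle <- function() {
  link_puzzle(3, list(list(color = 1, a = c(1, 1), b = c(1, 3)),
                      list(color = 2, a = c(2, 1), b = c(2, 3)),
                      list(color = 3, a = c(3, 1), b = c(3, 3))))
}

three_row_solution <- function() {
  link_solution(lapply(1:3, function(r) {
    list(color = r, cells = cbind(rep(r, 3), 1:3))
  }))
}

# Noiseless attempt table with t_m exactly linear in the level index.
linear_attempts <- function(n = 60, slope = 15, intercept = 20) {
  ladder <- build_ladder("match3")
  idx <- rep(1:10, length.out = n)
  data.frame(
    participant_id = rep(sprintf("L%02d", 1:3), length.out = n),
    game = "match3",
    level_index = idx,
    board_size = vapply(idx, function(i) ladder_level(ladder, i)$board_size, integer(1)),
    num_objects = vapply(idx, function(i) ladder_level(ladder, i)$num_objects, integer(1)),
    t_m = intercept + slope * idx,
    solved = TRUE,
    session_index = rep(1:20, length.out = n),
    stringsAsFactors = FALSE)
}
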