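test_that("generated puzzles ship a validating full-fill witness, deterministically", {
  for (rep in 1:8) {
    s <- sample(4:8, 1)
    g <- sample(4:8, 1)
    ps <- generate_puzzle(difficulty_level(s, g), seed = rep)
    expect_length(ps$puzzle$pairs, g)
    v <- validate_solution(ps$puzzle, ps$solution)
    expect_true(v$valid)
    covered <- do.call(rbind, lapply(ps$solution$paths, function(p) p$cells))
    expect_equal(nrow(covered), s * s)
    expect_equal(nrow(unique(covered)), s * s)
  }
  a <- generate_puzzle(difficulty_level(6, 5), seed = 11)
  b <- generate_puzzle(difficulty_level(6, 5), seed = 11)
  expect_identical(a$puzzle$pairs, b$puzzle$pairs)
  expect_identical(a$solution$paths, b$solution$paths)
})

test_that("minimum segment length relaxes only when the board cannot hold 3 cells per pair", {
  ps <- generate_puzzle(difficulty_level(4, 8), seed = 2)  # 16 cells, 8 pairs
  lens <- vapply(ps$solution$paths, function(p) nrow(p$cells), integer(1))
  expect_true(all(lens >= 2))
  ps <- generate_puzzle(difficulty_level(5, 8), seed = 2)  # 25 cells >= 24
  lens <- vapply(ps$solution$paths, function(p) nrow(p$cells), integer(1))
  expect_true(all(lens >= 3))
})

test_that("solver finds the unique three-row solution of the 3x3 worked example", {
  res <- solve_puzzle(three_row_puzzle())
  expect_equal(res$status, "solved")
  expect_true(validate_solution(three_row_puzzle(), res$solution)$valid)
  for (r in 1:3) {
    expect_equal(unname(res$solution$paths[[r]]$cells),
                 unname(cbind(rep(r, 3), 1:3)))
  }
  expect_equal(count_solutions(three_row_puzzle()), 1)
})

test_that("solver output always validates and search is deterministic", {
  for (rep in 1:10) {
    ps <- generate_puzzle(difficulty_level(5, sample(4:8, 1)), seed = 50 + rep)
    r1 <- solve_puzzle(ps$puzzle)
    r2 <- solve_puzzle(ps$puzzle)
    expect_equal(r1$status, "solved")
    expect_true(validate_solution(ps$puzzle, r1$solution)$valid)
    expect_identical(r1$solution$paths, r2$solution$paths)
  }
})

test_that("budget exhaustion is reported as unknown, not unsolvable", {
  ps <- generate_puzzle(difficulty_level(6, 4), seed = 9)
  res <- solve_puzzle(ps$puzzle, node_budget = 3)
  expect_equal(res$status, "unknown")
  expect_null(res$solution)
})

test_that("puzzles with shared endpoints or no pairs are rejected / unsolvable", {
  expect_error(link_puzzle(3, list(list(color = 1, a = c(1, 1), b = c(1, 3)),
                                   list(color = 2, a = c(1, 1), b = c(2, 3)))),
               "share")
  empty <- link_puzzle(3, list())
  expect_equal(solve_puzzle(empty)$status, "unsolvable")
  expect_equal(count_solutions(empty), 0)
})

test_that("validator names the first violated rule", {
  p <- three_row_puzzle()
  expect_true(validate_solution(p, three_row_solution())$valid)

  # a solution leaving row 4 uncovered on a 4x4 board
  p4 <- link_puzzle(4, list(list(color = 1, a = c(1, 1), b = c(1, 4)),
                            list(color = 2, a = c(2, 1), b = c(2, 4)),
                            list(color = 3, a = c(3, 1), b = c(3, 4)),
                            list(color = 4, a = c(4, 1), b = c(4, 4))))
  partial <- link_solution(lapply(1:3, function(r) {
    list(color = r, cells = cbind(rep(r, 4), 1:4))
  }))
  expect_equal(validate_solution(p4, partial)$reason, "path count mismatch")
  with_row4 <- link_solution(c(partial$paths,
                               list(list(color = 4, cells = rbind(c(4, 1), c(4, 2),
                                                                  c(4, 3), c(4, 4))))))
  expect_true(validate_solution(p4, with_row4)$valid)
  short_row4 <- link_solution(c(partial$paths,
                                list(list(color = 4, cells = rbind(c(4, 1), c(4, 2))))))
  expect_equal(validate_solution(p4, short_row4)$reason, "endpoint mismatch")

  # crossing paths that reuse a cell
  reuse <- three_row_solution()
  reuse$paths[[2]]$cells <- rbind(c(2, 1), c(1, 1), c(1, 2), c(2, 2), c(2, 3))
  expect_equal(validate_solution(p, reuse)$reason, "cell reuse")

  # uncovered cell with per-path rules intact: 2x2 board, one domino pair
  p2 <- link_puzzle(2, list(list(color = 1, a = c(1, 1), b = c(1, 2))))
  top <- link_solution(list(list(color = 1, cells = rbind(c(1, 1), c(1, 2)))))
  expect_equal(validate_solution(p2, top)$reason, "uncovered cell")

  broken <- three_row_solution()
  broken$paths[[1]]$cells <- rbind(c(1, 1), c(1, 3))
  expect_equal(validate_solution(p, broken)$reason, "nonadjacent step")
})

test_that("puzzle text serialization round-trips", {
  ps <- generate_puzzle(difficulty_level(5, 5), seed = 4)
  back <- parse_puzzle(format_puzzle(ps$puzzle))
  expect_equal(back$size, ps$puzzle$size)
  # endpoint sets per color match (orientation of a/b may flip on re-parse)
  for (k in seq_along(ps$puzzle$pairs)) {
    orig <- ps$puzzle$pairs[[k]]
    got <- back$pairs[[k]]
    expect_setequal(list(paste(orig$a, collapse = ","), paste(orig$b, collapse = ",")),
                    list(paste(got$a, collapse = ","), paste(got$b, collapse = ",")))
  }
})
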