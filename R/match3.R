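# Match-3 engine: board generation, match detection, swap validation and the
# remove / gravity / refill cascade. Boards are integer matrices of gem codes
# 1..num_types; EMPTY cells (mid-cascade only) are NA. Coordinates are 1-based
# (row, col) with row 1 at the top; gravity pulls gems toward higher row
# indices.

#' Construct a match-3 gem grid
#'
#' @param cells Integer matrix of gem codes in `1..num_types` (NA marks an
#'   empty cell mid-cascade; completed grids carry none).
#' @param num_types Size of the gem alphabet.
#' @return An object of class `gem_grid` with fields `cells`, `width`,
#'   `height`, `num_types`.
#' @export
#' @examples
#' g <- gem_grid(matrix(c(1,2,3,4, 2,3,4,1, 3,4,1,2, 4,1,2,3), 4, byrow = TRUE), 4)
#' find_matches(g)
gem_grid <- function(cells, num_types) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  stop_if_not_scalar_number(num_types, "num_types")
  num_types <- as.integer(num_types)
  if (num_types < 2) stop("num_types must be at least 2")
  codes <- cells[!is.na(cells)]
  if (length(codes) && (min(codes) < 1 || max(codes) > num_types)) {
    stop("cell codes must lie in 1..num_types")
  }
  structure(
    list(cells = cells, width = ncol(cells), height = nrow(cells),
         num_types = num_types),
    class = "gem_grid"
  )
}

#' @export
print.gem_grid <- function(x, ...) {
  cat(sprintf("<gem_grid> %dx%d, %d gem types\n", x$height, x$width, x$num_types))
  cat(format_grid(x))
  invisible(x)
}

#' Construct a swap move
#'
#' @param cell_a,cell_b Length-2 integer vectors `(row, col)`; the two cells
#'   must be orthogonally adjacent.
#' @return An object of class `swap_move`.
#' @export
swap_move <- function(cell_a, cell_b) {
  cell_a <- as.integer(cell_a); cell_b <- as.integer(cell_b)
  if (length(cell_a) != 2 || length(cell_b) != 2) stop("cells are (row, col) pairs")
  if (sum(abs(cell_a - cell_b)) != 1L) {
    stop("swap cells must be orthogonally adjacent")
  }
  structure(list(cell_a = cell_a, cell_b = cell_b), class = "swap_move")
}

in_bounds <- function(grid, cell) {
  all(cell >= 1L) && cell[1] <= grid$height && cell[2] <= grid$width
}

# Maximal runs >= 3 in one vector; returns start positions, lengths, codes.
runs_in_line <- function(v) {
  r <- rle(v)
  keep <- which(r$lengths >= 3 & !is.na(r$values))
  if (!length(keep)) return(NULL)
  starts <- cumsum(c(1L, r$lengths))[keep]
  data.frame(start = starts, length = r$lengths[keep], code = r$values[keep])
}

#' Find all matches on a grid
#'
#' Scans every row and column for maximal runs of at least three equal gem
#' codes. Runs longer than three are reported as a single descriptor; a gem
#' sitting at the intersection of a row run and a column run appears in both.
#'
#' @param grid A fully populated `gem_grid`.
#' @return A data frame with one row per match: `orientation` ("h"/"v"),
#'   `row`, `col` (start cell), `length` and `code`. Zero rows when the grid
#'   is matchless.
#' @export
find_matches <- function(grid) {
  stopifnot(inherits(grid, "gem_grid"))
  if (anyNA(grid$cells)) stop("grid has EMPTY cells; resolve the cascade first")
  out <- list()
  for (i in seq_len(grid$height)) {
    r <- runs_in_line(grid$cells[i, ])
    if (!is.null(r)) {
      out[[length(out) + 1L]] <- data.frame(
        orientation = "h", row = i, col = r$start, length = r$length, code = r$code)
    }
  }
  for (j in seq_len(grid$width)) {
    r <- runs_in_line(grid$cells[, j])
    if (!is.null(r)) {
      out[[length(out) + 1L]] <- data.frame(
        orientation = "v", row = r$start, col = j, length = r$length, code = r$code)
    }
  }
  if (!length(out)) {
    return(data.frame(orientation = character(), row = integer(),
                      col = integer(), length = integer(), code = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$orientation, res$row, res$col), , drop = FALSE]
}

#' Cells covered by match descriptors
#'
#' @param matches A data frame as returned by [find_matches()].
#' @return Two-column matrix of (row, col) cells, duplicates removed.
#' @export
match_cells <- function(matches) {
  if (nrow(matches) == 0) return(matrix(integer(), ncol = 2))
  cells <- do.call(rbind, lapply(seq_len(nrow(matches)), function(k) {
    m <- matches[k, ]
    if (m$orientation == "h") {
      cbind(m$row, m$col + seq_len(m$length) - 1L)
    } else {
      cbind(m$row + seq_len(m$length) - 1L, m$col)
    }
  }))
  unique(cells)
}

swap_cells <- function(cells, a, b) {
  tmp <- cells[a[1], a[2]]
  cells[a[1], a[2]] <- cells[b[1], b[2]]
  cells[b[1], b[2]] <- tmp
  cells
}

#' Test whether a swap is legal
#'
#' A swap is valid iff the two cells are orthogonally adjacent, hold different
#' codes, and the hypothetical swap creates at least one match.
#'
#' @param grid A fully populated `gem_grid`.
#' @param move A `swap_move`; out-of-bounds cells are an error.
#' @return TRUE or FALSE.
#' @export
is_valid_swap <- function(grid, move) {
  stopifnot(inherits(grid, "gem_grid"), inherits(move, "swap_move"))
  a <- move$cell_a; b <- move$cell_b
  if (!in_bounds(grid, a) || !in_bounds(grid, b)) {
    stop("swap cells out of bounds")
  }
  if (sum(abs(a - b)) != 1L) return(FALSE)
  if (grid$cells[a[1], a[2]] == grid$cells[b[1], b[2]]) return(FALSE)
  g2 <- grid
  g2$cells <- swap_cells(grid$cells, a, b)
  nrow(find_matches(g2)) > 0
}

#' Apply a swap and resolve the resulting cascade
#'
#' Repeats remove-matches, gravity-drop within columns, refill-from-top until
#' the grid is matchless. Refill gems are drawn uniformly from `1..num_types`
#' using the given seed, so identical `(grid, move, seed)` replays are
#' identical.
#'
#' @param grid A fully populated `gem_grid`.
#' @param move A valid `swap_move` (see [is_valid_swap()]); an invalid swap is
#'   an error and the grid is unchanged.
#' @param seed Integer seed for the refill stream.
#' @return A `cascade_result`: list with `final_grid`, `cascades` (resolution
#'   rounds), `cleared` (gems removed) and `per_round_matches`.
#' @export
apply_swap <- function(grid, move, seed) {
  stopifnot(inherits(grid, "gem_grid"))
  if (!is_valid_swap(grid, move)) stop("invalid swap for this grid")
  cells <- swap_cells(grid$cells, move$cell_a, move$cell_b)
  h <- grid$height
  with_seed(seed, {
    cascades <- 0L
    cleared <- 0L
    per_round <- list()
    repeat {
      g <- gem_grid(cells, grid$num_types)
      m <- find_matches(g)
      if (nrow(m) == 0) break
      cascades <- cascades + 1L
      per_round[[cascades]] <- m
      mc <- match_cells(m)
      cleared <- cleared + nrow(mc)
      cells[mc] <- NA_integer_
      # gravity then refill, column by column, top to bottom
      for (j in seq_len(ncol(cells))) {
        col <- cells[, j]
        kept <- col[!is.na(col)]
        n_new <- h - length(kept)
        refill <- if (n_new > 0) {
          sample.int(grid$num_types, n_new, replace = TRUE)
        } else integer()
        cells[, j] <- c(refill, kept)
      }
    }
    structure(
      list(final_grid = gem_grid(cells, grid$num_types),
           cascades = cascades, cleared = cleared,
           per_round_matches = per_round),
      class = "cascade_result"
    )
  })
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %d cascade round(s), %d gem(s) cleared\n",
              x$cascades, x$cleared))
  invisible(x)
}

#' List every valid swap on a grid
#'
#' Enumerates adjacent cell pairs in row-major order (each pair once, with
#' `cell_a` before `cell_b`) and keeps those for which [is_valid_swap()]
#' holds. Order is deterministic.
#'
#' @param grid A fully populated `gem_grid`.
#' @return List of `swap_move` objects (possibly empty).
#' @export
list_available_moves <- function(grid) {
  stopifnot(inherits(grid, "gem_grid"))
  moves <- list()
  for (i in seq_len(grid$height)) {
    for (j in seq_len(grid$width)) {
      for (nb in list(c(i, j + 1L), c(i + 1L, j))) {
        if (nb[1] > grid$height || nb[2] > grid$width) next
        mv <- swap_move(c(i, j), nb)
        if (is_valid_swap(grid, mv)) moves[[length(moves) + 1L]] <- mv
      }
    }
  }
  moves
}

#' Generate a playable match-3 board
#'
#' Fills the board cell by cell (row-major), rejection-sampling any code that
#' would complete a run of three with its two left or two upper neighbours,
#' then verifies at least one valid swap exists; otherwise the whole board is
#' resampled. The retry cap guards against impossible configurations, which
#' cannot occur within the 4..8 parameter ranges.
#'
#' @param level A `difficulty_level` (board size and gem alphabet).
#' @param seed Integer seed; identical seeds give identical boards.
#' @param max_retries Whole-board resample cap.
#' @return A matchless `gem_grid` with at least one available move.
#' @export
#' @examples
#' g <- generate_board(difficulty_level(4, 4), seed = 1)
#' nrow(find_matches(g)) # 0
generate_board <- function(level, seed, max_retries = 1000L) {
  stopifnot(inherits(level, "difficulty_level"))
  s <- level$board_size; k <- level$num_objects
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      cells <- matrix(NA_integer_, s, s)
      for (i in seq_len(s)) {
        for (j in seq_len(s)) {
          banned <- integer()
          if (j >= 3 && cells[i, j - 1L] == cells[i, j - 2L]) {
            banned <- c(banned, cells[i, j - 1L])
          }
          if (i >= 3 && cells[i - 1L, j] == cells[i - 2L, j]) {
            banned <- c(banned, cells[i - 1L, j])
          }
          allowed <- setdiff(seq_len(k), banned)
          cells[i, j] <- allowed[sample.int(length(allowed), 1L)]
        }
      }
      g <- gem_grid(cells, k)
      if (length(list_available_moves(g)) > 0) return(g)
    }
    stop("board generation failed: retry cap exhausted (configuration infeasible)")
  })
}

#' Serialize a grid as plain text
#'
#' One row per line, integer codes separated by spaces; `.` marks an empty
#' cell. [parse_grid()] inverts it.
#'
#' @param grid A `gem_grid`.
#' @return A single string.
#' @export
format_grid <- function(grid) {
  rows <- apply(grid$cells, 1, function(r) {
    paste(ifelse(is.na(r), ".", r), collapse = " ")
  })
  paste0(paste(rows, collapse = "\n"), "\n")
}

#' @rdname format_grid
#' @param text Text produced by [format_grid()].
#' @param num_types Gem alphabet size of the parsed grid.
#' @export
parse_grid <- function(text, num_types) {
  lines <- strsplit(trimws(text), "\n")[[1]]
  rows <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    as.integer(ifelse(toks == ".", NA, toks))
  })
  gem_grid(do.call(rbind, rows), num_types)
}
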