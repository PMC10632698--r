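#' Construct a difficulty level
#'
#' A difficulty level pairs a square board size with a number of unique game
#' objects (gem types for match-3, colored endpoint pairs for numberlink).
#' Both parameters range over 4..8, giving the 25-level ladder used by the
#' adaptive service.
#'
#' @param board_size Side length of the square board, in cells (4..8).
#' @param num_objects Number of unique game objects (4..8).
#' @param index Optional 1-based position within a ladder.
#' @return An object of class `difficulty_level` with fields `index`,
#'   `board_size` and `num_objects`.
#' @export
#' @examples
#' difficulty_level(4, 4, index = 1)
difficulty_level <- function(board_size, num_objects, index = NA_integer_) {
  stop_if_not_scalar_number(board_size, "board_size")
  stop_if_not_scalar_number(num_objects, "num_objects")
  if (board_size < 4 || board_size > 8) stop("board_size must lie in [4, 8]")
  if (num_objects < 4 || num_objects > 8) stop("num_objects must lie in [4, 8]")
  structure(
    list(index = as.integer(index), board_size = as.integer(board_size),
         num_objects = as.integer(num_objects)),
    class = "difficulty_level"
  )
}

#' @export
print.difficulty_level <- function(x, ...) {
  cat(sprintf("<difficulty_level> index %s: %dx%d board, %d objects\n",
              ifelse(is.na(x$index), "?", x$index), x$board_size,
              x$board_size, x$num_objects))
  invisible(x)
}

#' Build the difficulty ladder for a game
#'
#' Levels are ordered lexicographically by (board size, object count):
#' `index = (s - 4) * 5 + (g - 4) + 1` over the full ranges. Board growth
#' dominates difficulty, matching the introductory training progression
#' (4x4 then 5x5 then 6x6), so all object counts at a size precede the next
#' size.
#'
#' @param game `"match3"` or `"numberlink"`.
#' @param s_range Board sizes to include, each in 4..8.
#' @param g_range Object counts to include, each in 4..8.
#' @return An object of class `difficulty_ladder` holding the ordered levels.
#' @export
#' @examples
#' lad <- build_ladder("match3")
#' length(lad$levels) # 25
build_ladder <- function(game = c("match3", "numberlink"),
                         s_range = 4:8, g_range = 4:8) {
  game <- match.arg(game)
  s_range <- sort(unique(as.integer(s_range)))
  g_range <- sort(unique(as.integer(g_range)))
  if (length(s_range) == 0 || length(g_range) == 0) stop("empty range")
  if (any(s_range < 4 | s_range > 8)) stop("board sizes must lie in [4, 8]")
  if (any(g_range < 4 | g_range > 8)) stop("object counts must lie in [4, 8]")
  grid <- expand.grid(g = g_range, s = s_range)  # g varies fastest
  levels <- mapply(function(s, g, i) difficulty_level(s, g, index = i),
                   grid$s, grid$g, seq_len(nrow(grid)), SIMPLIFY = FALSE)
  structure(list(game = game, levels = levels), class = "difficulty_ladder")
}

#' @export
print.difficulty_ladder <- function(x, ...) {
  cat(sprintf("<difficulty_ladder> %s: %d levels (%dx%d/%d .. %dx%d/%d)\n",
              x$game, length(x$levels),
              x$levels[[1]]$board_size, x$levels[[1]]$board_size,
              x$levels[[1]]$num_objects,
              x$levels[[length(x$levels)]]$board_size,
              x$levels[[length(x$levels)]]$board_size,
              x$levels[[length(x$levels)]]$num_objects))
  invisible(x)
}

#' Retrieve a ladder level by index
#'
#' @param ladder A `difficulty_ladder`.
#' @param index 1-based level index.
#' @return The `difficulty_level` at that position.
#' @export
ladder_level <- function(ladder, index) {
  stopifnot(inherits(ladder, "difficulty_ladder"))
  index <- as.integer(index)
  if (is.na(index) || index < 1 || index > length(ladder$levels)) {
    stop(sprintf("level index %s outside ladder [1, %d]",
                 index, length(ladder$levels)))
  }
  ladder$levels[[index]]
}

#' Move along the ladder according to a level decision
#'
#' Shifts the current level index by the decision (-1 retreat, 0 stay,
#' +1 advance), clamped to the ladder ends: at the bottom a -1 and at the top
#' a +1 leave the index unchanged.
#'
#' @param ladder A `difficulty_ladder`.
#' @param current The current `difficulty_level` (must carry a ladder index).
#' @param decision -1, 0 or +1.
#' @return The new `difficulty_level`.
#' @export
next_level <- function(ladder, current, decision) {
  stopifnot(inherits(ladder, "difficulty_ladder"))
  if (!decision %in% c(-1L, 0L, 1L)) stop("decision must be -1, 0 or +1")
  idx <- if (inherits(current, "difficulty_level")) current$index else as.integer(current)
  if (is.na(idx) || idx < 1 || idx > length(ladder$levels)) {
    stop("current level is not positioned in the ladder")
  }
  new_idx <- min(max(idx + as.integer(decision), 1L), length(ladder$levels))
  ladder$levels[[new_idx]]
}
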