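# Numberlink engine. A puzzle is a square grid with colored endpoint pairs; a
# solution joins each pair by an orthogonal path such that no cell is used
# twice and every cell is covered (full-fill rule). Generation cuts a
# randomized Hamiltonian path into segments, so every emitted puzzle carries a
# full-fill witness by construction.

#' Construct a numberlink puzzle
#'
#' @param size Side length of the square grid.
#' @param pairs List of pairs, each `list(color =, a = c(row, col), b = c(row, col))`.
#'   Endpoints must be distinct cells, in bounds.
#' @return An object of class `link_puzzle`.
#' @export
link_puzzle <- function(size, pairs) {
  stop_if_not_scalar_number(size, "size")
  size <- as.integer(size)
  if (size < 2) stop("size must be at least 2")
  if (length(pairs)) {
    eps <- do.call(rbind, lapply(pairs, function(p) rbind(p$a, p$b)))
    if (any(eps < 1) || any(eps > size)) stop("endpoint out of bounds")
    if (anyDuplicated(paste(eps[, 1], eps[, 2]))) {
      stop("endpoints must be distinct cells (pairs share an endpoint)")
    }
    cols <- vapply(pairs, function(p) as.integer(p$color), integer(1))
    if (anyDuplicated(cols)) stop("pair colors must be unique")
  }
  pairs <- lapply(pairs, function(p) {
    list(color = as.integer(p$color), a = as.integer(p$a), b = as.integer(p$b))
  })
  structure(list(size = size, pairs = pairs), class = "link_puzzle")
}

#' Construct a numberlink solution
#'
#' @param paths List of paths, each `list(color =, cells = )` with `cells` an
#'   n x 2 matrix of (row, col) in visiting order.
#' @return An object of class `link_solution`.
#' @export
link_solution <- function(paths) {
  paths <- lapply(paths, function(p) {
    cells <- matrix(as.integer(p$cells), ncol = 2)
    list(color = as.integer(p$color), cells = cells)
  })
  structure(list(paths = paths), class = "link_solution")
}

#' @export
print.link_puzzle <- function(x, ...) {
  cat(sprintf("<link_puzzle> %dx%d, %d pairs\n", x$size, x$size, length(x$pairs)))
  cat(format_puzzle(x))
  invisible(x)
}

link_dirs <- matrix(c(-1L, 0L, 0L, -1L, 0L, 1L, 1L, 0L), ncol = 2, byrow = TRUE)

#' Validate a candidate solution against a puzzle
#'
#' Checks, in order: one path per pair with matching colors; path termini
#' equal the pair's endpoints (either orientation); consecutive cells
#' orthogonally adjacent and in bounds; no cell used twice across paths
#' ("cell reuse"); all cells covered ("uncovered cell").
#'
#' @param puzzle A `link_puzzle`.
#' @param candidate A `link_solution`.
#' @return List with `valid` (logical) and `reason` (`NA` when valid, else the
#'   first violated rule).
#' @export
validate_solution <- function(puzzle, candidate) {
  stopifnot(inherits(puzzle, "link_puzzle"), inherits(candidate, "link_solution"))
  fail <- function(reason) list(valid = FALSE, reason = reason)
  s <- puzzle$size
  if (length(candidate$paths) != length(puzzle$pairs)) {
    return(fail("path count mismatch"))
  }
  pair_by_color <- stats::setNames(puzzle$pairs,
                                   vapply(puzzle$pairs, function(p) p$color, integer(1)))
  seen <- matrix(FALSE, s, s)
  for (p in candidate$paths) {
    pr <- pair_by_color[[as.character(p$color)]]
    if (is.null(pr)) return(fail("unknown color"))
    cells <- p$cells
    if (any(cells < 1) || any(cells > s)) return(fail("cell out of bounds"))
    n <- nrow(cells)
    if (n < 2) return(fail("degenerate path"))
    ends_fwd <- all(cells[1, ] == pr$a) && all(cells[n, ] == pr$b)
    ends_rev <- all(cells[1, ] == pr$b) && all(cells[n, ] == pr$a)
    if (!ends_fwd && !ends_rev) return(fail("endpoint mismatch"))
    steps <- abs(diff(cells[, 1])) + abs(diff(cells[, 2]))
    if (any(steps != 1L)) return(fail("nonadjacent step"))
    for (i in seq_len(n)) {
      if (seen[cells[i, 1], cells[i, 2]]) return(fail("cell reuse"))
      seen[cells[i, 1], cells[i, 2]] <- TRUE
    }
  }
  if (!all(seen)) return(fail("uncovered cell"))
  list(valid = TRUE, reason = NA_character_)
}

# Randomized Hamiltonian path on an s x s grid: serpentine start, then
# "backbite" Markov moves (attach an end to a non-consecutive neighbour on the
# path and reverse the enclosed prefix). Caller supplies RNG state.
random_hamiltonian_path <- function(s, n_iter = 20L * s^3) {
  rows <- lapply(seq_len(s), function(i) {
    js <- if (i %% 2 == 1L) seq_len(s) else rev(seq_len(s))
    cbind(rep(i, s), js)
  })
  path <- do.call(rbind, rows)
  n <- nrow(path)
  pos <- matrix(0L, s, s)  # cell -> position in path
  pos[path] <- seq_len(n)
  for (it in seq_len(n_iter)) {
    if (stats::runif(1) < 0.5) {  # operate on a random end
      path <- path[rev(seq_len(n)), , drop = FALSE]
      pos[path] <- seq_len(n)
    }
    head <- path[1, ]
    nbr <- sweep(link_dirs, 2, head, `+`)
    ok <- nbr[, 1] >= 1 & nbr[, 1] <= s & nbr[, 2] >= 1 & nbr[, 2] <= s
    nbr <- nbr[ok, , drop = FALSE]
    ks <- pos[nbr]
    ks <- ks[ks >= 3L]
    if (!length(ks)) next
    k <- ks[sample.int(length(ks), 1L)]
    path[seq_len(k - 1L), ] <- path[(k - 1L):1L, , drop = FALSE]
    pos[path] <- seq_len(n)
  }
  path
}

#' Generate a numberlink puzzle with its witness solution
#'
#' Draws a random Hamiltonian path on the board (serpentine initialisation
#' randomized by backbite moves) and cuts it into exactly `num_objects`
#' segments; segment termini become the colored endpoint pairs and the
#' segments themselves are the witness solution, which therefore fills every
#' cell by construction. Minimum segment length is 3 cells, relaxed to 2 when
#' the board cannot hold `3 * num_objects` cells (size 4 with 7-8 pairs).
#'
#' @param level A `difficulty_level` (board size and pair count).
#' @param seed Integer seed; identical seeds give identical puzzles.
#' @return List with elements `puzzle` (a `link_puzzle`, endpoints only) and
#'   `solution` (the `link_solution` witness).
#' @export
#' @examples
#' ps <- generate_puzzle(difficulty_level(5, 5), seed = 3)
#' validate_solution(ps$puzzle, ps$solution)$valid
generate_puzzle <- function(level, seed) {
  stopifnot(inherits(level, "difficulty_level"))
  s <- level$board_size
  g <- level$num_objects
  if (s * s < 2L * g) stop("infeasible (size, pairs) combination")
  lmin <- if (s * s >= 3L * g) 3L else 2L
  with_seed(seed, {
    path <- random_hamiltonian_path(s)
    extra <- s * s - g * lmin
    lens <- lmin + tabulate(if (extra > 0) sample.int(g, extra, replace = TRUE)
                            else integer(), nbins = g)
    stops <- cumsum(lens)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    paths <- lapply(seq_len(g), function(i) {
      list(color = i, cells = path[starts[i]:stops[i], , drop = FALSE])
    })
    pairs <- lapply(paths, function(p) {
      list(color = p$color, a = p$cells[1, ], b = p$cells[nrow(p$cells), ])
    })
    list(puzzle = link_puzzle(s, pairs), solution = link_solution(paths))
  })
}

# Connected components of free cells (occ == 0). Returns a matrix of
# component labels, 0 where occupied.
free_components <- function(occ) {
  s <- nrow(occ)
  comp <- matrix(0L, s, s)
  label <- 0L
  for (start in which(occ == 0L)) {
    if (comp[start] > 0L) next
    label <- label + 1L
    stack <- start
    comp[start] <- label
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (cur - 1L) %% s + 1L
      j <- (cur - 1L) %/% s + 1L
      for (d in seq_len(4)) {
        ni <- i + link_dirs[d, 1]; nj <- j + link_dirs[d, 2]
        if (ni < 1 || ni > s || nj < 1 || nj > s) next
        idx <- (nj - 1L) * s + ni
        if (occ[idx] == 0L && comp[idx] == 0L) {
          comp[idx] <- label
          stack <- c(stack, idx)
        }
      }
    }
  }
  comp
}

# Labels of free components 4-adjacent to a cell.
adjacent_components <- function(comp, cell) {
  s <- nrow(comp)
  out <- integer()
  for (d in seq_len(4)) {
    ni <- cell[1] + link_dirs[d, 1]; nj <- cell[2] + link_dirs[d, 2]
    if (ni < 1 || ni > s || nj < 1 || nj > s) next
    if (comp[ni, nj] > 0L) out <- c(out, comp[ni, nj])
  }
  unique(out)
}

# Necessary-condition prune for the search at pair k with path head `head`.
# Sound: only provably dead states are cut.
link_prune_dead <- function(occ, comp, pairs, k, head) {
  np <- length(pairs)
  target <- pairs[[k]]$b
  head_comps <- adjacent_components(comp, head)
  # 1. target must be adjacent to head or to a free component adjacent to head
  if (sum(abs(head - target)) != 1L &&
      !any(adjacent_components(comp, target) %in% head_comps)) {
    return(TRUE)
  }
  anchors <- head_comps
  if (k < np) {
    for (j in (k + 1L):np) {
      ca <- adjacent_components(comp, pairs[[j]]$a)
      cb <- adjacent_components(comp, pairs[[j]]$b)
      # 2. pending pair endpoints must be mutually reachable through free cells
      if (sum(abs(pairs[[j]]$a - pairs[[j]]$b)) != 1L && !any(ca %in% cb)) {
        return(TRUE)
      }
      anchors <- c(anchors, ca, cb)
    }
  }
  # 3. no orphan free region: every component must touch the head or a pending
  # endpoint (a region touching only the current target can never be filled)
  labels <- unique(comp[comp > 0L])
  length(setdiff(labels, anchors)) > 0L
}

link_search <- function(puzzle, node_budget, count_all, cap) {
  s <- puzzle$size
  pairs <- puzzle$pairs
  np <- length(pairs)
  st <- new.env(parent = emptyenv())
  st$nodes <- 0L
  st$count <- 0L
  st$solution <- NULL
  st$aborted <- FALSE
  if (np == 0L) {
    return(list(status = "unsolvable", solution = NULL, count = 0L, nodes = 0L))
  }
  occ <- matrix(0L, s, s)
  for (p in pairs) {
    occ[p$a[1], p$a[2]] <- p$color
    occ[p$b[1], p$b[2]] <- p$color
  }
  record <- function(paths) {
    st$count <- st$count + 1L
    if (is.null(st$solution)) {
      st$solution <- link_solution(lapply(seq_len(np), function(i) {
        list(color = pairs[[i]]$color, cells = paths[[i]])
      }))
    }
  }
  extend <- function(k, occ, paths, cur) {
    if (st$aborted || (count_all && st$count >= cap) ||
        (!count_all && !is.null(st$solution))) return()
    st$nodes <- st$nodes + 1L
    if (st$nodes > node_budget) { st$aborted <- TRUE; return() }
    head <- cur[nrow(cur), ]
    target <- pairs[[k]]$b
    if (all(head == target)) {
      paths[[k]] <- cur
      if (k == np) {
        if (all(occ != 0L)) record(paths)
        return()
      }
      nk <- k + 1L
      extend(nk, occ, paths, matrix(pairs[[nk]]$a, 1))
      return()
    }
    for (d in seq_len(4)) {
      ni <- head[1] + link_dirs[d, 1]; nj <- head[2] + link_dirs[d, 2]
      if (ni < 1 || ni > s || nj < 1 || nj > s) next
      v <- occ[ni, nj]
      is_target <- ni == target[1] && nj == target[2]
      if (v != 0L && !is_target) next
      occ2 <- occ
      occ2[ni, nj] <- pairs[[k]]$color
      nxt <- c(ni, nj)
      if (!is_target) {
        comp <- free_components(occ2)
        if (link_prune_dead(occ2, comp, pairs, k, nxt)) next
      }
      extend(k, occ2, paths, rbind(cur, nxt))
    }
  }
  extend(1L, occ, vector("list", np), matrix(pairs[[1]]$a, 1))
  status <- if (!is.null(st$solution)) {
    "solved"
  } else if (st$aborted) {
    "unknown"
  } else {
    "unsolvable"
  }
  list(status = status, solution = st$solution, count = st$count, nodes = st$nodes)
}

#' Solve a numberlink puzzle by pruned backtracking
#'
#' Depth-first search routing the pairs in order, extending each path one cell
#' at a time in a fixed neighbour order (up, left, right, down), with sound
#' feasibility pruning (target reachability, pending-pair connectivity, no
#' orphan free region). Search order is deterministic.
#'
#' @param puzzle A `link_puzzle`.
#' @param node_budget Maximum search nodes before giving up.
#' @return List with `status` ("solved", "unsolvable" or "unknown" when the
#'   budget ran out) and `solution` (a `link_solution` or NULL). A returned
#'   solution always passes [validate_solution()].
#' @export
solve_puzzle <- function(puzzle, node_budget = 1e6) {
  stopifnot(inherits(puzzle, "link_puzzle"))
  res <- link_search(puzzle, node_budget, count_all = FALSE, cap = 1L)
  res[c("status", "solution", "nodes")]
}

#' Count distinct full-fill solutions
#'
#' Exhaustive version of the solver, intended as a test oracle on small
#' boards (size <= 6 recommended). Two solutions are distinct when any path
#' covers a different cell sequence (paths are oriented a to b).
#'
#' @param puzzle A `link_puzzle`.
#' @param cap Stop counting at this many solutions.
#' @param node_budget Maximum search nodes.
#' @return Integer count, truncated at `cap`.
#' @export
count_solutions <- function(puzzle, cap = 1000L, node_budget = 1e7) {
  stopifnot(inherits(puzzle, "link_puzzle"))
  res <- link_search(puzzle, node_budget, count_all = TRUE, cap = cap)
  res$count
}

#' Serialize a numberlink puzzle as text
#'
#' `.` for an empty cell, letters for endpoint pairs (color 1 = A, ...).
#' [parse_puzzle()] inverts it.
#'
#' @param puzzle A `link_puzzle` (at most 26 pairs for the letter encoding).
#' @return A single string.
#' @export
format_puzzle <- function(puzzle) {
  s <- puzzle$size
  chars <- matrix(".", s, s)
  for (p in puzzle$pairs) {
    chars[p$a[1], p$a[2]] <- LETTERS[p$color]
    chars[p$b[1], p$b[2]] <- LETTERS[p$color]
  }
  paste0(paste(apply(chars, 1, paste, collapse = " "), collapse = "\n"), "\n")
}

#' @rdname format_puzzle
#' @param text Text produced by [format_puzzle()].
#' @export
parse_puzzle <- function(text) {
  lines <- strsplit(trimws(text), "\n")[[1]]
  chars <- do.call(rbind, lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]]))
  s <- nrow(chars)
  if (ncol(chars) != s) stop("puzzle grid must be square")
  pairs <- list()
  for (letter in intersect(LETTERS, unique(c(chars)))) {
    where <- which(chars == letter, arr.ind = TRUE)
    if (nrow(where) != 2) stop(sprintf("endpoint '%s' must appear exactly twice", letter))
    pairs[[length(pairs) + 1L]] <- list(color = match(letter, LETTERS),
                                        a = where[1, ], b = where[2, ])
  }
  link_puzzle(s, pairs)
}
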