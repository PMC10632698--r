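# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All randomized operations in the package are pure
# functions of (inputs, seed) via this helper.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed
#'
#' Hashes a parent seed with one or more integer strata (player, session,
#' game, ...) into a new seed below 2^31 - 1, so nested simulations can draw
#' independent, replayable random streams from one master seed.
#'
#' @param seed Parent integer seed.
#' @param ... Integer strata.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1103515245 + as.numeric(p) + 12345) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
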