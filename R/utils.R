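# Internal helpers: seed management and argument checks.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state. All exported stochastic functions route their randomness through
# this, which is what makes them pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named RNG stream seed
#'
#' Deterministically mixes a base seed with extra integer or character tags
#' into a new 31-bit seed. The pipeline uses this to give every stage (and
#' every community tie-break) its own named stream, so re-running one stream
#' never perturbs another.
#'
#' @param seed base integer seed.
#' @param ... integer or character tags naming the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483629
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% 2147483629
  }
  as.integer(h + 1)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

stop_if_not_fraction <- function(x, name, lo = 0, hi = 1,
                                 open_lo = FALSE, open_hi = FALSE) {
  bad <- !is.numeric(x) || length(x) != 1L || !is.finite(x) ||
    (if (open_lo) x <= lo else x < lo) ||
    (if (open_hi) x >= hi else x > hi)
  if (bad) stop(sprintf("`%s` must lie in %s%g, %g%s", name,
                        if (open_lo) "(" else "[", lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
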