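# Internal helpers: classed error conditions, RNG hygiene, small numerics.

fila_stop <- function(subclass, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("filaclock_", subclass, "_error"),
                                     "filaclock_error")))
}

fila_assert <- function(cond, subclass, msg) {
  if (!isTRUE(cond)) fila_stop(subclass, msg)
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so that library internals (e.g. the
#' bootstrap) are deterministic without disturbing user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a 32-bit-safe child seed from a root seed and a stream index.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

# Centered moving mean with shrinking windows at the edges (k odd).
moving_mean <- function(y, k = 5L) {
  n <- length(y)
  if (n == 0L || k <= 1L) return(y)
  h <- (as.integer(k) - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Snap times to the frame grid defined by origin t0 and step dt.
snap_to_grid <- function(t, dt, t0 = 0) t0 + round((t - t0) / dt) * dt

# Nearly-equal comparison for time grids.
near <- function(a, b, tol = 1e-8) abs(a - b) < tol

format_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
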