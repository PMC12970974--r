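#' Derive a child seed from a root seed
#'
#' Reproducibility in the simulation grids follows a counter scheme: every
#' (level, size, replicate) cell of a grid draws from its own stream whose
#' seed is a deterministic mix of the root seed and the integer indices.
#' Any sub-grid can therefore be regenerated in isolation.
#'
#' The mix is a Lehmer-style congruential fold modulo 2^31 - 1, so derived
#' seeds always fit in a 32-bit integer.
#'
#' @param seed integer root seed.
#' @param ... further non-negative integer indices (level, size index, ...).
#' @return a single integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  for (k in c(length(idx), idx)) {
    stopifnot(is.finite(k), k >= 0)
    # 48271 is a primitive root mod m (MINSTD multiplier)
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All samplers route through this so
# that draws are bit-reproducible and never disturb the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
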