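#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one global seed into per-cell / per-trajectory sub-seeds by a
#' splittable counter (an LCG step on the master seed plus stream index),
#' so that simulations are reproducible regardless of how work is split.
#'
#' @param seed master integer seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' sub_seed(1L, 0:3)
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  # 64-bit safe modular arithmetic via doubles (< 2^53)
  m <- 2147483647 # 2^31 - 1 (Mersenne prime modulus)
  s <- (as.double(seed) %% m) + 1
  x <- (s * 48271 + as.double(stream) * 16807 + 1) %% m
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `expr` with the RNG seeded locally; restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
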