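# Seed fan-out: one master seed is split into independent child seeds for
# folds, iterations, niches and operators, so any sub-experiment can be
# replayed in isolation without consuming the parent stream.

#' Derive a child seed from a master seed and a path of indices
#'
#' Mixes the master seed with an arbitrary sequence of non-negative integers
#' (a "path" identifying the sub-experiment) through a multiplicative integer
#' hash. The result is a valid R seed in `[1, 2^31 - 2]`, and distinct paths
#' map to well-separated seeds.
#'
#' @param master Integer master seed.
#' @param ... Non-negative integers identifying the sub-stream
#'   (e.g. fold index, iteration index, niche index).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(master, ...) {
  path <- c(as.numeric(master), as.numeric(c(...)))
  # 64-bit-safe mixing on doubles: stay below 2^53 by reducing mod 2^31-1
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (v in path) {
    h <- (h * 48271 + (v %% m) + 1) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
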