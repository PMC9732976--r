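#' Derive a child seed from a master seed and integer indices
#'
#' Deterministically folds a master seed and any number of integer indices
#' (run, replicate, image, ...) into a single seed below 2^31, so that every
#' stochastic stage of a study draws from its own reproducible stream. The
#' scheme is a multiply-accumulate hash modulo the Mersenne prime 2^31 - 1;
#' all intermediate products stay below 2^53 and are therefore exact in
#' double precision.
#'
#' @param seed master seed (non-negative integer).
#' @param ... integer indices identifying the child stream.
#' @return A single integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' child_seed(1, 3, 2) # run 3, replicate 2 under master seed 1
#' @export
child_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0)
  m <- 2147483647 # 2^31 - 1
  s <- as.numeric(seed) %% m
  for (k in idx) {
    stopifnot(is.finite(k))
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(max(1, s))
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-away-from-zero; base round() uses round-half-even
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
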