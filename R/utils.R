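#' @keywords internal
"_PACKAGE"

## Numeric helpers shared across modules. All randomness in the package is
## funnelled through explicit integer seeds; nested generators derive
## sub-seeds with derive_seed() so that one top-level seed reproduces the
## whole pipeline bit-for-bit.

sigmoid <- function(x) 1 / (1 + exp(-x))

## Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  m <- apply(u, 1L, max)
  e <- exp(u - m)
  e / rowSums(e)
}

#' Derive a reproducible sub-seed from a base seed and a tag
#'
#' Deterministically maps (seed, tag) to an integer in `[0, 2^31 - 1)` so
#' that independent generators sharing one user-facing seed draw from
#' unrelated RNG streams.
#'
#' @param seed integer base seed.
#' @param tag character label of the consuming component.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

## Run expr with a local RNG state seeded by `seed`; restores the caller's
## RNG afterwards so library code never perturbs user-level randomness.
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

## Uniform random matrix in [-a, a]; the default scale follows the usual
## fan-based heuristic for dense layers.
rand_mat <- function(nr, nc, scale = sqrt(6 / (nr + nc))) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

stop_value <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
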