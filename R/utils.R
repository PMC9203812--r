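#' @importFrom methods is
#' @importFrom stats rpois rlnorm runif quantile approx median setNames
#' @importFrom utils head tail write.table read.table
NULL

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream. All stochastic operations in the package funnel through this
## so that a `seed` argument gives bit-identical results regardless of what
## the session did before.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

#' Derive a per-stage seed from a global seed
#'
#' Hashes a stage name into a deterministic offset so that every pipeline
#' stage has an independent, reproducible RNG stream while the user supplies
#' a single global seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, nzchar(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 2038 + h + 1) %% 2147483587L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
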