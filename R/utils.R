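# Seed-scoped random number generation. All randomness in the package flows
# through one of these generators so that runs are reproducible from a single
# integer seed and never disturb (or depend on) the caller's RNG state.

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}

rng_sample <- function(rng, x, n) with_rng(rng, sample(x, n))
rng_rnorm <- function(rng, n, mean = 0, sd = 1) with_rng(rng, stats::rnorm(n, mean, sd))
rng_runif <- function(rng, n, min = 0, max = 1) with_rng(rng, stats::runif(n, min, max))
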