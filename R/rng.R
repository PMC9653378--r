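#' Named random-number streams
#'
#' All randomness in a simulated session flows from one session seed through
#' named sub-streams (targets, user jitter, encoder noise, ...) so that the
#' same component draws the same numbers whether a session is generated in
#' open loop or inside the closed-loop engine.
#'
#' A stream is an environment holding a private copy of R's RNG state;
#' [with_stream()] swaps that state in, evaluates an expression, and swaps it
#' back out, leaving the global RNG untouched.
#'
#' @param seed integer master seed.
#' @param name stream name; hashed together with the seed.
#' @return an object of class `rng_stream`.
#' @keywords internal
make_stream <- function(seed, name) {
  sub <- derive_seed(seed, name)
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(sub)
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env$name <- name
  class(env) <- "rng_stream"
  env
}

#' Evaluate an expression under a stream's RNG state
#' @param stream an `rng_stream`.
#' @param expr expression drawing random numbers.
#' @keywords internal
with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Deterministic 31-bit sub-seed from (seed, name); small string hash keeps
# distinct streams decorrelated without external dependencies.
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435761 + h) %% 2147483647)
}
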