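#' Derive a child seed from a parent seed and an index path
#'
#' All stochastic stages (splitting, search, per-fold model fits) consume
#' seeds derived from one user-facing seed via a fixed multiplicative
#' congruence, so each stage is individually reproducible and no two stages
#' share an RNG stream.  Results stay below 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param ... one or more integer indices identifying the child stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- abs(as.double(seed)) %% m
  for (k in c(...)) {
    x <- (x * 48271 + abs(as.double(k)) * 1299709 + 1) %% m
  }
  as.integer(x)
}

# Evaluate `code` under its own RNG stream without disturbing the caller's.
preserve_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# round-half-up, used for per-class train counts (R's round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

abort <- function(..., class = "moostack_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
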