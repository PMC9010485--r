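#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed}, so seeded package operations
#' never disturb the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression.
#' @return value of \code{code}
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic small substream offset from a string label
seed_offset <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 10000L
}

# derive a per-operation seed below 2^31
derive_seed <- function(seed, label) {
  (as.integer(seed) %% 100000L) * 10007L + seed_offset(label)
}
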