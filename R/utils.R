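# Internal RNG helpers. All user-facing randomness flows through a single
# integer seed; stages derive their own sub-seeds with derive_seed() so a
# stage can be re-run in isolation and reproduce the pipeline's draws.

MAX_SEED <- 2147483646L

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic fan-out of one integer seed into per-stage seeds, so that
#' individual pipeline stages can be rerun in isolation yet reproduce the
#' draws they made inside a full pipeline run.
#'
#' @param seed integer global seed.
#' @param stage single string naming the stage (e.g. `"simulate"`, `"split"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stage) == 1)
  # cheap string hash (polynomial rolling, modular) -- stable across platforms
  h <- 0
  for (cp in utf8ToInt(as.character(stage))) h <- (h * 131 + cp) %% MAX_SEED
  as.integer((abs(seed) %% MAX_SEED + h * 7919) %% MAX_SEED + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
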