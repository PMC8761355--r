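# Seed plumbing. All user-facing randomness takes an explicit integer seed;
# `with_seed()` evaluates code under that seed while preserving the caller's
# RNG state, so library code never clobbers a user's stream.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-individual seed from a master seed
#'
#' Stable 31-bit polynomial hash of the individual label combined with the
#' master seed, so per-individual RNG streams do not depend on the order in
#' which (or how concurrently) individuals are processed.
#'
#' @param master_seed Integer master seed.
#' @param individual_id Character label.
#' @return A single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, individual_id) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(as.character(individual_id)))
    h <- (h * 31 + code) %% m
  as.integer(h)
}
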