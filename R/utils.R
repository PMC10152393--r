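# Small internal helpers.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Nearest valid key suggestion for config validation.
nearest_key <- function(key, valid) {
  d <- utils::adist(key, valid, ignore.case = TRUE)
  valid[which.min(d)]
}
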